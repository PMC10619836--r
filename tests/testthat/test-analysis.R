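test_that("zero-offspring fraction matches the reference tabulation", {
  bins <- reference_bins()
  lrs <- lrs_from_bins(bins$offspring, bins$n)
  expect_equal(length(lrs), sum(bins$n))
  tab <- data.frame(offspring = lrs)
  expect_equal(round(zero_offspring_fraction(tab), 3), 0.584)
  expect_equal(zero_offspring_fraction(data.frame(offspring = c(0, 0, 0))), 1)
  expect_error(zero_offspring_fraction(data.frame(offspring = numeric(0))),
               "empty")
})

test_that("stratified reproduction probabilities are empirical frequencies", {
  # constructed table reproducing the published 0.28 / 0.12 contrast
  tab <- data.frame(
    tailfat = c(rep(40, 100), rep(30, 100)),
    offspring = c(rep(1, 28), rep(0, 72), rep(1, 12), rep(0, 88)))
  p <- offspring_probability(tab, "tailfat", 35, k = 1)
  expect_equal(unname(p), c(0.28, 0.12))
  expect_equal(fitness_ratio(tab, "tailfat", 35, k = 1), 0.28 / 0.12)
  # at-least mode counts any reproduction
  tab$offspring[1:5] <- 3
  p2 <- offspring_probability(tab, "tailfat", 35, k = 1, mode = "at_least")
  expect_equal(unname(p2["above"]), 0.28)
  # identical strata give a ratio of exactly 1
  tab2 <- data.frame(tailfat = rep(c(30, 40), each = 50),
                     offspring = rep(c(0, 1), 50))
  expect_equal(fitness_ratio(tab2, "tailfat", 35), 1)
  # an empty stratum is flagged, not silently dropped
  expect_warning(p3 <- offspring_probability(tab, "tailfat", 0, k = 1),
                 "empty stratum")
  expect_true(is.na(p3["below"]))
})

test_that("ability-independent offspring give a null ratio near 1", {
  set.seed(44)
  n <- 20000
  tab <- data.frame(tailfat = runif(n, 11.4, 64.6),
                    offspring = rbinom(n, 1, 0.2))
  r <- fitness_ratio(tab, "tailfat", 35, k = 1)
  expect_lt(abs(r - 1), 0.12)
})

test_that("bin summary reproduces hand arithmetic on a toy table", {
  tab <- data.frame(
    offspring = c(0, 0, 2),
    tailfat = c(30, 40, 50), detection_range = c(4, 5, 6),
    dominance = c(0, 0.1, -0.1), bite_force = c(0.1, 0.12, 0.08),
    hearing = c(0, 0, 0.2), binocular_vision = c(0.4, 0.5, 0.6),
    mass = c(2000, 2200, 2600))
  tab$energy_budget <- daily_meat_requirement(tab$mass)
  bs <- bin_summary(tab)
  expect_equal(bs$bin, c(0, 2))
  expect_equal(bs$n, c(2L, 1L))
  expect_equal(bs$tailfat, c(35, 50))
  expect_equal(bs$mass, c(2100, 2600))
  expect_equal(bs$energy_budget,
               c(mean(daily_meat_requirement(c(2000, 2200))),
                 daily_meat_requirement(2600)))
  # degenerate single-bin table
  expect_equal(nrow(bin_summary(tab[tab$offspring == 0, ])), 1)
})

test_that("scavenger abilities rise across offspring bins in a default run", {
  tab <- fitness_table(default_run())
  bs <- bin_summary(tab)
  expect_gt(cor(bs$bin, bs$tailfat, method = "spearman"), 0)
  expect_gt(cor(bs$bin, bs$detection_range, method = "spearman"), 0)
})

test_that("successful-stratum means behave on toys and flag emptiness", {
  tab <- data.frame(offspring = c(0, 1, 2), mass = c(1900, 2000, 3000),
                    tailfat = c(30, 40, 44))
  s <- successful_mass_mean(tab)
  expect_equal(s$mass, 2500)
  expect_equal(s$tailfat, 42)
  expect_equal(s$n, 2L)
  expect_warning(s0 <- successful_mass_mean(
    data.frame(offspring = 0, mass = 2000, tailfat = 40)), "no reproduct")
  expect_true(is.na(s0$mass))
})

test_that("reproductive-success density is a proper probability density", {
  tab <- data.frame(offspring = c(rep(0, 60), rep(1, 25), rep(2, 10),
                                  rep(5, 5)))
  d <- reproductive_success_density(tab)
  expect_equal(stats::integrate(d$pdf, -Inf, Inf)$value, 1,
               tolerance = 1e-6)
  # degenerate point mass: unimodal peak at the common count
  d2 <- reproductive_success_density(data.frame(offspring = rep(2, 50)))
  expect_lt(abs(d2$x[which.max(d2$y)] - 2), d2$bw)
  expect_equal(stats::integrate(d2$pdf, -Inf, Inf)$value, 1,
               tolerance = 1e-6)
})

test_that("high-tailfat stratum carries more density at one offspring", {
  tab <- fitness_table(default_run())
  hi <- reproductive_success_density(tab[tab$tailfat > 35, ])
  lo <- reproductive_success_density(tab[tab$tailfat <= 35, ])
  expect_gt(hi$pdf(1), lo$pdf(1))
})

test_that("yearly composition frequencies are proper distributions", {
  fit <- default_run()
  comp <- composition_timeseries(fit)
  sums <- tapply(comp$freq, interaction(comp$year, comp$trait, drop = TRUE),
                 sum)
  sums <- sums[!is.na(sums)]
  expect_true(all(abs(sums - 1) < 1e-9))
  # founder cohorts (initial and immigrant) are class-uniform
  r <- fit$records
  founders <- r[r$parent == 0, ]
  for (tr in c("tailfat", "bite_force")) {
    tabf <- table(factor(founders[[paste0(tr, "_class")]],
                         levels = expression_levels()))
    expect_gt(chisq.test(tabf, p = rep(0.2, 5))$p.value, 0.01)
  }
})

test_that("permuting abilities flattens the fitness ratio to 1", {
  set.seed(9)
  tab <- fitness_table(default_run())
  tab$tailfat <- sample(tab$tailfat)
  r <- fitness_ratio(tab, "tailfat", 35, k = 1)
  expect_lt(abs(r - 1), 0.15)
})
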