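test_that("class bounds scale to the published per-trait ability ranges", {
  b <- factor_bounds()
  # tailfat: 38 kg x factor
  expect_equal(unname(38 * b), unname(cbind(
    c(11.4, 24.7, 34.2, 41.8, 51.3), c(24.7, 34.2, 41.8, 51.3, 64.6))))
  # carcass detection: 5 km x factor
  expect_equal(unname(5 * b), unname(cbind(
    c(1.5, 3.25, 4.5, 5.5, 6.75), c(3.25, 4.5, 5.5, 6.75, 8.5))))
  # prey detection (binocular vision): 0.5 km x factor
  expect_equal(unname(0.5 * b), unname(cbind(
    c(0.15, 0.325, 0.45, 0.55, 0.675),
    c(0.325, 0.45, 0.55, 0.675, 0.85))))
})

test_that("ability scaling matches its anchor points", {
  expect_equal(ability_value("tailfat", 1.7), 64.6)
  expect_equal(ability_value("detection_range", 0.3), 1.5)
  expect_equal(ability_value("dominance", 0.77), -0.23)
  expect_equal(ability_value("bite_force", 1.0), 0.1)
  expect_equal(ability_value("hearing", 1.0), 0)
  expect_equal(ability_value("binocular_vision", 1.1), 0.55)
  expect_error(ability_value("wingspan", 1), "unknown trait")
})

test_that("factors map to exactly one class (half-open bounds, closed top)", {
  expect_equal(expression_of_factor(c(0.3, 0.65, 0.9, 1.1, 1.35, 1.7)),
               c("extra_small", "small", "medium", "big", "extra_big",
                 "extra_big"))
  expect_equal(expression_of_factor(0.65 - 1e-9), "extra_small")
  expect_error(expression_of_factor(1.71))
})

test_that("founder genomes are uniform over classes and in-bounds", {
  set.seed(101)
  draws <- replicate(4000, sample_genome(), simplify = FALSE)
  facs <- vapply(draws, function(g) g$factor, numeric(6))
  expect_true(all(facs >= 0.3 & facs <= 1.7))
  expect_true(all(vapply(draws, function(g)
    identical(g$trait, trait_names()), logical(1))))
  cls <- vapply(draws, function(g) g$expression, character(6))
  for (i in seq_len(6)) {
    tab <- table(factor(cls[i, ], levels = expression_levels()))
    expect_gt(chisq.test(tab, p = rep(0.2, 5))$p.value, 0.01)
  }
})

test_that("inheritance kernel is the 80/10/10 scheme with folded edges", {
  P <- expression_transition_matrix()
  expect_equal(unname(rowSums(P)), rep(1, 5))
  expect_equal(unname(diag(P)), rep(0.8, 5))
  # transitions only between identical or adjacent classes
  adj <- abs(row(P) - col(P)) <= 1
  expect_true(all(P[!adj] == 0))
  # edge classes fold the stray 10% onto their single neighbour
  expect_equal(P["extra_small", "small"], 0.2)
  expect_equal(P["extra_big", "big"], 0.2)
  expect_equal(P["medium", "small"], 0.1)
  # irreducible and aperiodic: some power is strictly positive
  P4 <- P %*% P %*% P %*% P
  expect_true(all(P4 > 0))
  # shortest extra_small -> extra_big chain spans 4 inheritance steps
  reach <- function(n) {
    M <- diag(5)
    for (i in seq_len(n)) M <- M %*% P
    M[1, 5] > 0
  }
  expect_false(reach(3))
  expect_true(reach(4))
})

test_that("offspring expression frequencies match the kernel empirically", {
  set.seed(7)
  draws <- offspring_expression("medium", n = 1e5)
  tab <- table(factor(draws, levels = expression_levels()))
  expect_equal(unname(tab[c("extra_small", "extra_big")]), c(0L, 0L),
               ignore_attr = TRUE)
  expect_gt(chisq.test(tab[c("small", "medium", "big")],
                       p = c(0.1, 0.8, 0.1))$p.value, 0.01)
  # edge parent never jumps past its neighbour
  xs <- offspring_expression("extra_small", n = 1e4)
  expect_true(all(xs %in% c("extra_small", "small")))
})

test_that("genome inheritance respects class adjacency and factor bounds", {
  set.seed(42)
  parent <- sample_genome()
  parent$expression <- rep("medium", 6)
  parent$factor <- rep(1.0, 6)
  for (i in 1:50) {
    kid <- inherit_genome(parent)
    expect_true(all(kid$expression %in% c("small", "medium", "big")))
    b <- factor_bounds()
    idx <- match(kid$expression, expression_levels())
    expect_true(all(kid$factor >= b[idx, "lo"] & kid$factor < b[idx, "hi"] |
                      (kid$expression == "extra_big" & kid$factor <= 1.7)))
    expect_equal(kid$ability,
                 ability_value(kid$trait, kid$factor))
  }
  # identical seed -> identical offspring genome
  set.seed(99); a <- inherit_genome(parent)
  set.seed(99); b2 <- inherit_genome(parent)
  expect_identical(a, b2)
  # copy-when-same-class policy keeps the parental factor
  set.seed(5)
  kid <- inherit_genome(parent, policy = "copy_when_same")
  same <- kid$expression == "medium"
  expect_true(all(kid$factor[same] == 1.0))
})
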