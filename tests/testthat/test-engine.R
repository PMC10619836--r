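test_that("configuration rejects invalid fields with named diagnostics", {
  expect_error(allosim_config(years = 0), "years")
  expect_error(allosim_config(birth_rate = 2), "birth_rate")
  expect_error(allosim_config(max_allosaurs = 5, init_allosaurs = 12),
               "max_allosaurs")
  expect_error(allosim_config(init_carcasses = 9), "init_carcasses")
  expect_error(allosim_config(starvation_frac = 1.2), "starvation_frac")
  expect_error(allosim_config(trait_table = data.frame(trait = "x")),
               "trait_table")
  expect_s3_class(allosim_config(years = 1), "allosim_config")
})

test_that("a one-year smoke run exercises every phase", {
  fit <- logged_run()
  r <- fit$records
  expect_gte(nrow(r), 12)
  expect_true(all(c("feed", "carcass_spawn", "carcass_removed", "starve",
                    "birth") %in% fit$events$type))
  expect_equal(nrow(fit$daily), fit$config$days)
  expect_true(all(r$offspring >= 0))
  expect_true(all(r$cause %in% c("starvation", "censored")))
  expect_true(all(is.na(r$died_day) == (r$cause == "censored")))
})

test_that("population caps and floors hold on every single day", {
  fit <- default_run()
  d <- fit$daily
  expect_true(all(d[, "allosaurs"] <= fit$config$max_allosaurs))
  expect_true(all(d[, "prey"] >= fit$config$min_prey))
  expect_true(all(d[, "sauropod_carcasses"] <= fit$config$carcass_cap))
  # predation opportunities outnumber scavenging opportunities >= 4:1
  expect_true(all(d[, "prey"] / pmax(d[, "sauropod_carcasses"], 1) >= 4))
})

test_that("identical configuration and seed give bit-identical trajectories", {
  a <- allosim(allosim_config(years = 2), seed = 123)
  b <- allosim(allosim_config(years = 2), seed = 123)
  expect_identical(a$records, b$records)
  expect_identical(a$daily, b$daily)
  expect_identical(a$counters, b$counters)
})

test_that("genealogy closes: every non-founder is someone's counted child", {
  fit <- default_run()
  r <- fit$records
  founders <- sum(r$parent == 0)
  expect_equal(founders, fit$counters$founders)
  expect_equal(sum(r$offspring), nrow(r) - founders)
  # every recorded parent id exists and was born before its child
  kids <- r[r$parent > 0, ]
  expect_true(all(kids$parent %in% r$id))
  expect_true(all(r$born_day[kids$parent] <= kids$born_day))
})

test_that("meat mass is conserved between agents and carcasses", {
  fit <- logged_run()
  ct <- fit$counters
  expect_equal(ct$total_intake, ct$total_consumed)
  # spawned mass fully partitions into consumption, decay, removed residual
  # and the standing stock at the end of the run
  expect_equal(ct$total_spawned_mass,
               ct$total_consumed + ct$total_decayed +
                 ct$total_removed_residual + ct$standing_carcass_mass,
               tolerance = 1e-9)
  # per-day ledgers agree too
  expect_equal(fit$daily[, "intake"], fit$daily[, "consumed"])
})

test_that("engine inheritance and abilities agree with the R primitives", {
  fit <- logged_run()
  r <- fit$records
  lv <- expression_levels()
  tt <- default_trait_table()
  for (tr in trait_names()) {
    f <- r[[paste0(tr, "_factor")]]
    expect_true(all(f >= 0.3 & f <= 1.7))
    expect_equal(r[[tr]], ability_value(rep(tr, nrow(r)), f, tt))
    expect_equal(r[[paste0(tr, "_class")]], expression_of_factor(f))
  }
  # parent-child expression ranks differ by at most one class
  kids <- r[r$parent > 0, ]
  for (tr in trait_names()) {
    pk <- match(r[[paste0(tr, "_class")]][kids$parent], lv)
    kk <- match(kids[[paste0(tr, "_class")]], lv)
    expect_true(all(abs(pk - kk) <= 1))
  }
})

test_that("daily intake never exceeds the fat-storage cap", {
  fit <- logged_run()
  f <- fit$events[fit$events$type == "feed", ]
  tf <- fit$records$tailfat[f$agent]
  expect_true(all(f$value <= tf + 1e-9))
  # one feeding event per agent per day
  expect_false(any(duplicated(f[c("day", "agent")])))
})

test_that("births happen at the configured per-agent daily rate", {
  # ungated configuration isolates the Bernoulli birth rule
  fit <- allosim(allosim_config(years = 4, birth_cost_kg = 0,
                                birth_min_mass = 0), seed = 17)
  d <- fit$daily
  open <- d[, "allosaurs"] < fit$config$max_allosaurs
  p_hat <- sum(d[open, "births"]) / sum(d[open, "allosaurs"])
  n <- sum(d[open, "allosaurs"])
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(p_hat - 0.02), 4 * se + 1e-3)
})

test_that("an empty world still runs and returns an empty record set", {
  fit <- allosim(allosim_config(years = 1, init_allosaurs = 0,
                                refound_on_extinction = FALSE), seed = 1)
  expect_equal(nrow(fit$records), 0)
  expect_equal(nrow(fit$daily), 365)
  expect_true(all(fit$daily[, "allosaurs"] == 0))
})

test_that("print and summary methods report the headline quantities", {
  fit <- default_run()
  expect_output(print(fit), "agents produced")
  s <- summary(fit)
  expect_s3_class(s, "summary.allosim")
  expect_output(print(s), "tailfat fitness ratio")
  expect_equal(s$agents_produced, nrow(fit$records))
  # plotting runs silently to a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, type = "composition"))
  expect_invisible(plot(fit, type = "lrs"))
})
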