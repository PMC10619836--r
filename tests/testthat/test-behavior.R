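test_that("perception is carrion-first with trait-specific radii", {
  carc <- rbind(c(4, 0))
  prey <- rbind(c(0.3, 0))
  hit <- perceive(c(0, 0), detection_range = 5, binocular_vision = 0.5,
                  carcass_pos = carc, prey_pos = prey)
  expect_equal(hit$kind, "carcass")
  expect_equal(hit$distance, 4)
  # carcass out of range, prey in range
  hit <- perceive(c(0, 0), 3, 0.5, carc, prey)
  expect_equal(hit$kind, "prey")
  # prey just beyond the binocular radius
  hit <- perceive(c(0, 0), 3, 0.5, carc, rbind(c(0.6, 0)))
  expect_equal(hit$kind, "none")
  # nothing at all
  hit <- perceive(c(0, 0), 5, 0.5, matrix(numeric(0), 0, 2),
                  matrix(numeric(0), 0, 2))
  expect_equal(hit$kind, "none")
})

test_that("feeding contests run in dominance order under hard caps", {
  # dominant feeds first when little remains
  set.seed(2)
  intake <- resolve_feeding(current_mass = 2050, initial_mass = 10000,
                            dominance = c(-0.23, 0.1), tailfat = c(40, 40))
  expect_equal(intake, c(10, 40))
  # full carcass: everyone eats to its own cap
  intake <- resolve_feeding(10000, 10000, c(0, 0.2, -0.1), c(41, 38, 25))
  expect_equal(intake, c(41, 38, 25))
  # availability exhausted mid-queue
  intake <- resolve_feeding(2010, 10000, c(1, 0), c(40, 40))
  expect_equal(intake, c(10, 0))
  # properties over random contests
  for (i in 1:30) {
    n <- sample(1:6, 1)
    cur <- runif(1, 2000, 20000); init <- 20000
    tf <- runif(n, 11.4, 64.6)
    out <- resolve_feeding(cur, init, rnorm(n), tf)
    expect_true(all(out <= tf + 1e-12))
    expect_lte(sum(out), max(0, cur - 0.2 * init) + 1e-9)
  }
})

test_that("hearing slows pursued prey with clamping", {
  expect_equal(prey_flight_speed(0.5), 1.5)
  expect_equal(prey_flight_speed(0), 3)
  expect_equal(prey_flight_speed(-0.7), 5.1)
  expect_equal(prey_flight_speed(0.9), 0.9)   # clamped at 0.3 x base
  expect_equal(prey_flight_speed(-2), 5.1)    # clamped at 1.7 x base
})

test_that("pursuit kinematics: interception, stalemate, and escape", {
  # strong hearing advantage: guaranteed interception, kill iff strike lands
  set.seed(1)
  out <- pursue_and_attack(0.4, hearing_ability = 0.5, bite_ability = 1)
  expect_equal(out$outcome, "kill")
  expect_equal(out$days, 1)
  # equal speeds: the gap never closes, pursuit ends by giving up
  out <- pursue_and_attack(0.4, 0, bite_ability = 1, max_days = 10)
  expect_equal(out$outcome, "abandoned")
  # faster prey: sight lost once the gap exceeds the binocular radius
  out <- pursue_and_attack(0.4, -0.5, bite_ability = 1,
                           binocular_vision = 0.5)
  expect_equal(out$outcome, "lost")
})

test_that("kill frequency per strike converges to the bite ability", {
  set.seed(33)
  n <- 3000
  kills <- sum(replicate(n, {
    pursue_and_attack(0.3, 0.5, bite_ability = 0.1)$outcome == "kill"
  }))
  expect_gt(binom.test(kills, n, p = 0.1)$p.value, 0.01)
})

test_that("interception rate rises with hearing ability", {
  set.seed(12)
  rate <- vapply(c(0.02, 0.05, 0.1), function(h) {
    hits <- replicate(500, {
      gap <- runif(1, 0.1, 0.5)
      pursue_and_attack(gap, h, bite_ability = 1,
                        max_days = 1L)$outcome %in% c("kill", "escape")
    })
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) > 0))
})
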