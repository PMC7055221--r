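test_that("hinge fit recovers noise-free generated parameters almost exactly", {
  p <- 1:9
  e <- pmax(0, 16.3 * (p - 3.478))
  f <- fit_hinge(p, e)
  expect_equal(f$gfr_est, 16.3, tolerance = 1e-3)
  expect_equal(f$threshold_est, 3.478, tolerance = 1e-3)
  expect_identical(f$tm_pi_est, f$gfr_est * f$threshold_est)
})

test_that("degenerate inputs raise named errors", {
  expect_error(fit_hinge(1:9, rep(0, 9)),
               class = "phoskin_error_degenerate_fit")
  expect_error(fit_hinge(c(1, 2, 3), c(0, 1, 2)),
               class = "phoskin_error_degenerate_fit") # too few points
  capped <- fit_hinge(1:9, pmax(0, 16.3 * (1:9 - 3.5)), theta_max = 0.5)
  expect_lte(capped$threshold_est, 0.5)
})

test_that("hinge minimizer agrees with an independent brute-force search", {
  set.seed(404)
  for (rep in 1:6) {
    n <- sample(8:12, 1)
    p <- sort(runif(n, 0, 9))
    theta <- runif(1, 2, 5)
    g <- runif(1, 8, 25)
    e <- pmax(0, g * (p - theta)) * exp(rnorm(n, 0, 0.1))
    f <- fit_hinge(p, e)
    b <- brute_hinge(p, e)
    expect_lt(abs(f$threshold_est - b$theta), 0.011)
    expect_lte(f$sse, b$sse + 1e-6)
  }
})

test_that("scaling the excretion axis scales slope and Tm, not the threshold", {
  set.seed(7)
  p <- sort(runif(10, 1, 9))
  e <- pmax(0, 15 * (p - 3.2)) + c(0.3, -0.2, 0.1, 0, -0.1, 0.2, -0.3, 0.1,
                                   0, -0.2)
  e <- pmax(0, e)
  f1 <- fit_hinge(p, e)
  f2 <- fit_hinge(p, 3.7 * e)
  expect_equal(f2$gfr_est, 3.7 * f1$gfr_est, tolerance = 1e-6)
  expect_equal(f2$tm_pi_est, 3.7 * f1$tm_pi_est, tolerance = 1e-6)
  expect_equal(f2$threshold_est, f1$threshold_est, tolerance = 1e-6)
})

test_that("noise-free simulator trajectories are recovered to < 0.1%", {
  tr <- simulate_cohort(quiet_config())$details$A01
  s <- tr$series
  keep <- s$time >= 0 & round(s$time * 10) %% 50 == 0
  f <- fit_hinge(s$plasma_pi[keep], s$renal[keep])
  expect_lt(abs(f$gfr_est - tr$gfr) / tr$gfr, 1e-3)
  expect_lt(abs(f$threshold_est - tr$threshold) / tr$threshold, 1e-3)
  expect_lt(abs(f$tm_pi_est - tr$tm_pi) / tr$tm_pi, 1e-3)
})

test_that("cohort estimator recovers a noiseless homogeneous cohort closely", {
  sim <- simulate_cohort(quiet_config(n_animals = 3))
  f <- fit_titration(sim$dataset)
  expect_equal(f$gfr_est, 16.3, tolerance = 0.02)
  expect_equal(f$threshold_est, 3.478, tolerance = 0.03)
  expect_equal(f$tm_pi_est, 56.7, tolerance = 0.05)
})

test_that("plateau window estimates Tm directly", {
  # published mean pairs over the mid-infusion window
  tm <- plateau_tm(table1$filtered, table1$excreted, window = 3:6)
  expect_equal(as.numeric(tm), 57.65)
  # noise-free saturated simulator collections return the generating Tm
  tr <- simulate_cohort(quiet_config())$details$A01
  pts <- data.frame(f = tr$gfr * tr$plasma$plasma_pi_mmol_l,
                    e = excretion_rate(tr$urine$urine_volume_ml,
                                       tr$urine$urine_pi_mmol_l,
                                       tr$urine$t_start_min,
                                       tr$urine$t_end_min))
  sat <- which(tr$plasma$time_min >= 22.5)
  expect_equal(as.numeric(plateau_tm(pts$f, pts$e, window = sat)),
               tr$tm_pi, tolerance = 0.03)
  expect_error(plateau_tm(pts$f, pts$e, window = 1:4, threshold_load = 56.7),
               class = "phoskin_error_below_threshold")
  expect_error(plateau_tm(pts$f, pts$e, window = 1),
               class = "phoskin_error_empty_window")
})

test_that("bootstrap is deterministic and needs at least 3 animals", {
  sim <- simulate_cohort(simulation_config(n_animals = 4, rng_seed = 12))
  f1 <- bootstrap_fit(sim$dataset, n_boot = 50, seed = 3)
  f2 <- bootstrap_fit(sim$dataset, n_boot = 50, seed = 3)
  expect_identical(f1$bootstrap_ci, f2$bootstrap_ci)
  expect_true(all(f1$bootstrap_ci[, "lower"] <= f1$bootstrap_ci[, "upper"]))
  two <- simulate_cohort(simulation_config(n_animals = 2, rng_seed = 12))
  expect_error(bootstrap_fit(two$dataset, n_boot = 10),
               class = "phoskin_error_degenerate_fit")
})
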