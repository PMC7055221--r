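test_that("threshold-linear excretion model matches hand arithmetic", {
  expect_equal(renal_excretion_model(3.478, 16.3, 56.7), 0)
  expect_equal(renal_excretion_model(0, 16.3, 56.7), 0)
  expect_equal(renal_excretion_model(7.9, 16.3, 56.7), 72.07)
  # ultrafilterable correction scales the filtered load
  expect_equal(renal_excretion_model(7.9, 16.3, 56.7, f_uf = 0.9),
               0.9 * 16.3 * 7.9 - 56.7)
})

test_that("splayed excretion stays in [0, F] and recovers the sharp limit", {
  p <- seq(0, 10, by = 0.25)
  for (s in c(5, 20, 80)) {
    e <- renal_excretion_model(p, 16.3, 56.7, splay = s)
    filt <- 16.3 * p
    expect_true(all(e >= 0 & e <= filt + 1e-12))
  }
  e_small <- renal_excretion_model(p, 16.3, 56.7, splay = 1e-8)
  expect_equal(e_small, renal_excretion_model(p, 16.3, 56.7), tolerance = 1e-6)
})

test_that("baseline is a pre-infusion steady state and excretion obeys the threshold", {
  sim <- simulate_animal(quiet_config(), body_weight = 3.28,
                         protocol = infusion_protocol())
  s <- sim$truth$series
  pre <- s$plasma_pi[s$time <= 0]
  expect_equal(pre, rep(2.2, length(pre)), tolerance = 1e-12)
  # with zero splay, excretion is exactly zero wherever P <= Tm/GFR
  below <- s$plasma_pi <= sim$truth$threshold
  expect_true(all(s$renal[below] == 0))
  expect_true(all(s$renal[!below] > 0))
})

test_that("plasma rises then plateaus near the observed trajectory", {
  sim <- simulate_animal(quiet_config(), body_weight = 3.28,
                         protocol = infusion_protocol())
  p <- sim$truth$plasma
  expect_true(all(diff(p$plasma_pi_mmol_l) > 0))
  # early rise is steeper than the late approach to the plateau
  expect_gt(p$plasma_pi_mmol_l[3] - p$plasma_pi_mmol_l[1],
            p$plasma_pi_mmol_l[8] - p$plasma_pi_mmol_l[6])
  # plateau close to the observed 7.9 mmol/L
  expect_equal(p$plasma_pi_mmol_l[p$time_min == 82.5], 7.9, tolerance = 0.02)
})

test_that("mass is conserved: trapezoidal re-integration closes the balance", {
  tr <- simulate_cohort(quiet_config())$details$A01
  s <- tr$series
  t_span <- max(s$time) - min(s$time)
  input <- trapz(s$time, s$infusion) + tr$j_base * t_span
  output <- (tail(s$pool, 1) - s$pool[1]) + trapz(s$time, s$renal) +
    trapz(s$time, s$extrarenal)
  expect_lt(abs(input - output) / input, 1e-6)
})

test_that("collections integrate the instantaneous series", {
  tr <- simulate_cohort(quiet_config())$details$A01
  s <- tr$series
  u <- tr$urine
  for (i in seq_len(nrow(u))) {
    seg <- s$time >= u$t_start_min[i] & s$time <= u$t_end_min[i]
    amount <- trapz(s$time[seg], s$renal[seg])
    # trapezoidal re-integration has O(h^2) error at the threshold kink
    expect_equal(u$urine_volume_ml[i] * u$urine_pi_mmol_l[i], amount,
                 tolerance = 1e-4)
  }
})

test_that("steady-state plasma is monotone in infusion, extrarenal clearance and Tm", {
  end_p <- function(rate = 120, kx = 5, tm = 56.7) {
    prot <- infusion_protocol(pi_infusion_rate = rate)
    sim <- simulate_animal(quiet_config(extrarenal_clearance = kx,
                                        tm_pi = tm),
                           3.28, prot)
    tail(sim$truth$series$plasma_pi, 1)
  }
  rates <- sapply(c(60, 120, 240), function(r) end_p(rate = r))
  expect_true(all(diff(rates) > 0))
  kxs <- sapply(c(2, 5, 12), function(k) end_p(kx = k))
  expect_true(all(diff(kxs) < 0))
  tms <- sapply(c(30, 56.7, 120), function(tm) end_p(tm = tm))
  expect_true(all(diff(tms) > 0))
})

test_that("cohorts are deterministic and substream-stable", {
  cfg <- simulation_config(n_animals = 3, rng_seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dataset$plasma, b$dataset$plasma)
  expect_identical(a$dataset$urine, b$dataset$urine)
  expect_identical(a$truth, b$truth)
  # adding a 4th animal does not perturb the first three
  d <- simulate_cohort(simulation_config(n_animals = 4, rng_seed = 9))
  expect_identical(d$truth[1:3, ], a$truth)
  expect_identical(d$dataset$plasma[d$dataset$plasma$animal_id != "A04", ],
                   a$dataset$plasma)
})

test_that("a homogeneous noiseless 1-animal cohort equals simulate_animal", {
  cfg <- quiet_config()
  coh <- simulate_cohort(cfg)
  one <- simulate_animal(cfg, body_weight = cfg$mean_body_weight,
                         protocol = infusion_protocol(), animal_id = "A01")
  expect_equal(coh$dataset$plasma$plasma_pi_mmol_l,
               one$plasma$plasma_pi_mmol_l)
  expect_equal(coh$dataset$urine$urine_pi_mmol_l, one$urine$urine_pi_mmol_l)
})

test_that("measurement noise is multiplicative with the configured CV", {
  cfg <- simulation_config(n_animals = 30, rng_seed = 5,
                           interanimal_cv_gfr = 0, interanimal_cv_tm = 0,
                           interanimal_cv_weight = 0)
  sim <- simulate_cohort(cfg)
  truth <- do.call(rbind, lapply(sim$details, function(d) d$plasma))
  ratio <- sim$dataset$plasma$plasma_pi_mmol_l / truth$plasma_pi_mmol_l
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(ratio), 0.10, tolerance = 0.02)
})
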