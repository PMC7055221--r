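#' Threshold-linear renal phosphate excretion
#'
#' Saturation-kinetics model of tubular Pi reabsorption: the nephrons
#' reabsorb the filtered load `F = f_uf * gfr * P` completely up to the
#' transport maximum `tm_pi`, so urinary excretion is `max(0, F - tm_pi)`.
#' A positive `splay` rounds the transition (nephron heterogeneity):
#' reabsorption becomes `min(F, tm_pi * F / (F + splay))`, which recovers
#' the sharp threshold as `splay -> 0` and keeps excretion within
#' `[0, F]`.
#'
#' @param plasma_pi Plasma Pi concentration P, mmol/L (vectorised).
#' @param gfr Glomerular filtration rate, mL/min.
#' @param tm_pi Tubular transport maximum for Pi, µmol/min.
#' @param f_uf Ultrafilterable fraction of plasma Pi, in (0, 1].
#' @param splay Splay constant, µmol/min; 0 gives the sharp threshold.
#' @return Urinary Pi excretion rate, µmol/min.
#' @export
#' @examples
#' renal_excretion_model(7.9, gfr = 16.3, tm_pi = 56.7)  # 72.07
renal_excretion_model <- function(plasma_pi, gfr, tm_pi, f_uf = 1, splay = 0) {
  stopifnot(all(plasma_pi >= 0), gfr >= 0, tm_pi >= 0, splay >= 0)
  filt <- f_uf * gfr * plasma_pi
  if (splay == 0) {
    pmax(0, filt - tm_pi)
  } else {
    reab <- pmin(filt, tm_pi * filt / (filt + splay))
    filt - reab
  }
}

#' Configuration of the synthetic phosphate-loading experiment
#'
#' Parameterizes the forward model: a single well-mixed extracellular pool
#' of volume `V_d(t) = distribution_volume_per_kg * body_weight +
#' volume_expansion_rate * t` receives the infusion plus a constant
#' endogenous input chosen so the baseline plasma concentration is a
#' pre-infusion steady state, and loses Pi through threshold-linear renal
#' excretion ([renal_excretion_model()]) and a linear extrarenal clearance
#' of the plasma excess above baseline.
#'
#' Defaults are the published loading experiment in the acidotic rabbit:
#' GFR 16.3 mL/min, TmPi 56.7 µmol/min, baseline plasma Pi 2.2 mmol/L,
#' and an extrarenal clearance of 5.0 mL/min, calibrated so the
#' simulated plasma and excretion plateaus match the observed ones
#' (about 7.9 mmol/L and 74 µmol/min at the end of loading).
#'
#' @param gfr Mean glomerular filtration rate, mL/min.
#' @param tm_pi Mean tubular transport maximum, µmol/min.
#' @param splay_constant Splay, µmol/min (0 = sharp threshold).
#' @param extrarenal_clearance Linear clearance k_x of plasma Pi above
#'   baseline by non-renal routes, mL/min.
#' @param baseline_plasma Pre-infusion plasma Pi P0, mmol/L.
#' @param distribution_volume_per_kg Pi distribution volume, mL/kg
#'   (default 200, the extracellular fluid fraction).
#' @param volume_expansion_rate Rate of ECF expansion during infusion,
#'   mL/min; `NULL` (default) means the infusate volumetric rate.
#' @param baseline_urine_flow Urine flow at baseline plasma Pi, mL/min.
#' @param diuresis_coefficient Extra urine flow per unit plasma Pi excess,
#'   mL/min per mmol/L.
#' @param noise_cv_plasma,noise_cv_urine_conc,noise_cv_urine_volume
#'   Multiplicative lognormal measurement noise CVs (dimensionless).
#' @param interanimal_cv_gfr,interanimal_cv_tm,interanimal_cv_weight
#'   Lognormal between-animal CVs for GFR, TmPi and body weight.
#' @param mean_body_weight Mean body weight, kg.
#' @param n_animals Cohort size.
#' @param rng_seed Root seed; each animal gets a deterministic substream.
#' @param ode_step Fixed integration step, min.
#' @return An object of class `simulation_config` (named list).
#' @export
simulation_config <- function(gfr = 16.3,
                              tm_pi = 56.7,
                              splay_constant = 0,
                              extrarenal_clearance = 5.0,
                              baseline_plasma = 2.2,
                              distribution_volume_per_kg = 200,
                              volume_expansion_rate = NULL,
                              baseline_urine_flow = 0.4,
                              diuresis_coefficient = 0.07,
                              noise_cv_plasma = 0.10,
                              noise_cv_urine_conc = 0.10,
                              noise_cv_urine_volume = 0.15,
                              interanimal_cv_gfr = 0.20,
                              interanimal_cv_tm = 0.20,
                              interanimal_cv_weight = 0.16,
                              mean_body_weight = 3.28,
                              n_animals = 6,
                              rng_seed = 1L,
                              ode_step = 0.1) {
  cfg <- as.list(environment())
  num <- setdiff(names(cfg), "volume_expansion_rate")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      pk_stop("phoskin_error_invalid_config",
              sprintf("config field '%s' must be a finite nonnegative number", f))
    }
  }
  for (f in c("gfr", "tm_pi", "baseline_plasma", "distribution_volume_per_kg",
              "mean_body_weight", "ode_step")) {
    if (cfg[[f]] <= 0) {
      pk_stop("phoskin_error_invalid_config",
              sprintf("config field '%s' must be strictly positive", f))
    }
  }
  if (cfg$n_animals < 1) {
    pk_stop("phoskin_error_invalid_config", "n_animals must be >= 1")
  }
  cfg$n_animals <- as.integer(cfg$n_animals)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "simulation_config")
}

# lognormal multiplier with unit mean and given CV
#' @noRd
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# deterministic per-animal substream: adding animal i+1 never perturbs
# animals 1..i
#' @noRd
animal_seed <- function(rng_seed, i) {
  as.integer((as.numeric(rng_seed) + 99991 * as.numeric(i)) %% 2147483647)
}

#' Simulate one animal through the phosphate-loading protocol
#'
#' Integrates the single-pool mass balance
#' `dQ/dt = I(t) + J_base - E(P) - X(P)` with `P = Q / V_d(t)`,
#' `E` the threshold-linear renal excretion, `X = k_x * max(0, P - P0)`
#' the extrarenal clearance and `J_base = E(P0) + X(P0)` the constant
#' endogenous input that makes `P0` a pre-infusion steady state.
#' Fixed-step classical Runge-Kutta (deSolve, method "rk4") on a grid of
#' `ode_step` minutes; cumulative renal, extrarenal and infused fluxes are
#' carried as extra state variables so mass closure is exact to rounding.
#'
#' Urine collections integrate `E` over each interval; urine volume
#' integrates `baseline_urine_flow + diuresis_coefficient * max(0, P-P0)`;
#' the recorded concentration is amount/volume. Plasma is sampled at each
#' interval midpoint. Multiplicative lognormal noise at the configured CVs
#' is applied to the measurements only; the returned truth record keeps
#' the noise-free series.
#'
#' @param config A [simulation_config()].
#' @param body_weight Body weight of this animal, kg.
#' @param protocol An [infusion_protocol()].
#' @param animal_id Identifier used in the returned tables.
#' @param gfr,tm_pi Per-animal values (default: the config means).
#' @return List with `plasma`, `urine` (measurement data.frames in the
#'   [pi_experiment()] schema) and `truth`: the generating parameters, the
#'   noise-free versions of both tables, the instantaneous series
#'   (`time`, `plasma_pi`, `renal`, `extrarenal`, `infusion`, `volume`)
#'   and the endogenous input `j_base`.
#' @export
simulate_animal <- function(config, body_weight, protocol,
                            animal_id = "A1",
                            gfr = config$gfr, tm_pi = config$tm_pi) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(protocol, "infusion_protocol"))
  f_uf <- 1 # the model's threshold is expressed on ultrafilterable plasma
  exp_rate <- config$volume_expansion_rate %||% infusate_flow(protocol)
  v0 <- config$distribution_volume_per_kg * body_weight
  p0 <- config$baseline_plasma
  kx <- config$extrarenal_clearance
  j_base <- renal_excretion_model(p0, gfr, tm_pi, f_uf,
                                  config$splay_constant) # + X(p0) = 0
  t_pre <- -protocol$pre_infusion_control_interval
  t_end <- protocol$infusion_duration
  h <- config$ode_step

  deriv <- function(t, y, infus) {
    vol <- v0 + exp_rate * max(0, t)
    p <- y[["Q"]] / vol
    if (p < 0) {
      pk_stop("phoskin_error_integration",
              "pool mass went negative; use a smaller ode_step")
    }
    e <- renal_excretion_model(p, gfr, tm_pi, f_uf, config$splay_constant)
    x <- kx * max(0, p - p0)
    uflow <- config$baseline_urine_flow +
      config$diuresis_coefficient * max(0, p - p0)
    list(c(infus + j_base - e - x, e, x, infus, uflow))
  }
  # integrate the control and loading periods separately so the infusion
  # step at t = 0 never leaks into a Runge-Kutta stage of the other segment
  y0 <- c(Q = p0 * v0, cumE = 0, cumX = 0, cumI = 0, cumVol = 0)
  t1 <- t_pre + h * (0:round(-t_pre / h))
  pre <- deSolve::ode(y = y0, times = t1, func = deriv, parms = 0,
                      method = "rk4")
  t2 <- h * (0:round(t_end / h))
  post <- deSolve::ode(y = pre[nrow(pre), -1], times = t2, func = deriv,
                       parms = protocol$pi_infusion_rate, method = "rk4")
  sol <- as.data.frame(rbind(pre[-nrow(pre), ], post))
  times <- sol$time
  vol_t <- v0 + exp_rate * pmax(0, sol$time)
  p_t <- sol$Q / vol_t
  e_t <- renal_excretion_model(p_t, gfr, tm_pi, f_uf, config$splay_constant)
  x_t <- kx * pmax(0, p_t - p0)
  i_t <- ifelse(sol$time >= 0 & sol$time < t_end,
                protocol$pi_infusion_rate, 0)

  # collection grid: control interval then consecutive intervals to t_end
  ci <- protocol$collection_interval
  starts <- c(t_pre, seq(0, t_end - ci, by = ci))
  ends <- starts + ci
  idx_of <- function(t) {
    i <- which.min(abs(times - t))
    if (abs(times[i] - t) > h / 2 + 1e-9) {
      pk_stop("phoskin_error_integration",
              "collection boundaries must lie on the integration grid")
    }
    i
  }
  at <- function(v, t) v[vapply(t, idx_of, integer(1))]
  mids <- (starts + ends) / 2
  amount <- at(sol$cumE, ends) - at(sol$cumE, starts)
  volume <- at(sol$cumVol, ends) - at(sol$cumVol, starts)
  conc <- ifelse(volume > 0, amount / volume, 0)
  p_mid <- at(p_t, mids)

  n_coll <- length(starts)
  plasma_true <- data.frame(animal_id = animal_id, time_min = mids,
                            plasma_pi_mmol_l = p_mid)
  urine_true <- data.frame(animal_id = animal_id, t_start_min = starts,
                           t_end_min = ends, urine_volume_ml = volume,
                           urine_pi_mmol_l = conc)
  plasma <- plasma_true
  urine <- urine_true
  plasma$plasma_pi_mmol_l <- p_mid * ln_noise(n_coll, config$noise_cv_plasma)
  urine$urine_volume_ml <- volume * ln_noise(n_coll,
                                             config$noise_cv_urine_volume)
  urine$urine_pi_mmol_l <- conc * ln_noise(n_coll, config$noise_cv_urine_conc)

  list(plasma = plasma,
       urine = urine,
       truth = list(animal_id = animal_id, body_weight = body_weight,
                    gfr = gfr, tm_pi = tm_pi,
                    threshold = tm_pi / (f_uf * gfr),
                    extrarenal_clearance = kx, j_base = j_base,
                    v0 = v0, expansion_rate = exp_rate,
                    plasma = plasma_true, urine = urine_true,
                    series = data.frame(time = sol$time, plasma_pi = p_t,
                                        renal = e_t, extrarenal = x_t,
                                        infusion = i_t, volume = vol_t,
                                        pool = sol$Q, cum_renal = sol$cumE,
                                        cum_extrarenal = sol$cumX,
                                        cum_infused = sol$cumI)))
}

#' Simulate a cohort of animals through the loading protocol
#'
#' Draws per-animal GFR, TmPi and body weight from lognormal distributions
#' with the configured between-animal CVs around the config means, runs
#' [simulate_animal()] for each, and assembles a ready-to-analyse
#' [pi_experiment()]. Each animal uses a deterministic substream of
#' `rng_seed`, so extending the cohort never changes earlier animals.
#'
#' @param config A [simulation_config()].
#' @param protocol An [infusion_protocol()]; defaults to the standard
#'   loading protocol.
#' @return List with `dataset` (a [pi_experiment()]) and `truth`: a
#'   data.frame of per-animal generating parameters plus a `details` list
#'   of per-animal truth records from [simulate_animal()].
#' @export
simulate_cohort <- function(config, protocol = infusion_protocol()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_animals
  plasma <- list(); urine <- list(); details <- list()
  truth <- data.frame(animal_id = character(n), body_weight = numeric(n),
                      gfr = numeric(n), tm_pi = numeric(n),
                      threshold = numeric(n))
  for (i in seq_len(n)) {
    id <- sprintf("A%02d", i)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(animal_seed(config$rng_seed, i))
    bw <- config$mean_body_weight * ln_noise(1, config$interanimal_cv_weight)
    gfr_i <- config$gfr * ln_noise(1, config$interanimal_cv_gfr)
    tm_i <- config$tm_pi * ln_noise(1, config$interanimal_cv_tm)
    sim <- simulate_animal(config, bw, protocol, animal_id = id,
                           gfr = gfr_i, tm_pi = tm_i)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    plasma[[i]] <- sim$plasma
    urine[[i]] <- sim$urine
    details[[id]] <- sim$truth
    truth[i, "animal_id"] <- id
    truth[i, c("body_weight", "gfr", "tm_pi", "threshold")] <-
      c(bw, gfr_i, tm_i, sim$truth$threshold)
  }
  animals <- data.frame(animal_id = truth$animal_id,
                        body_weight_kg = truth$body_weight)
  dataset <- pi_experiment(protocol, animals,
                           do.call(rbind, plasma), do.call(rbind, urine))
  list(dataset = dataset, truth = truth, details = details)
}
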