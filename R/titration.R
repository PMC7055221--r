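#' Fit the threshold-linear (hinge) titration model
#'
#' Fits `E = max(0, g * (P - theta))` to (plasma Pi, urinary excretion)
#' pairs by weighted least squares: for each candidate threshold `theta`
#' on a grid of `grid_resolution` spanning `[0, max(P)]`, the slope `g`
#' has the closed form `sum(w E (P-theta)) / sum(w (P-theta)^2)` over the
#' points above `theta` (points at or below contribute `w E^2` to the
#' SSE); the global grid minimizer is then refined by one golden-section
#' pass over its bracketing grid cell. Ties at the grid minimum break
#' toward the smaller threshold. The slope estimates the phosphate-derived
#' GFR (GFR_Pi), the threshold estimates TmPi/GFR, and their product
#' estimates TmPi.
#'
#' @param plasma_pi Plasma Pi values P, mmol/L (>= 0).
#' @param excreted Matching excretion rates E, µmol/min.
#' @param weights Optional nonnegative weights (default 1).
#' @param grid_resolution Threshold grid spacing, mmol/L. Default 0.01.
#' @param min_above Minimum number of points required strictly above the
#'   fitted threshold. Default 3.
#' @param theta_max Upper bound for the threshold grid, mmol/L. Default
#'   `Inf` (the grid spans `[0, max(P)]`).
#' @return An object of class `titration_fit`: list with `gfr_est`
#'   (mL/min), `threshold_est` (mmol/L), `tm_pi_est` (µmol/min, equal to
#'   `gfr_est * threshold_est`), `sse`, `n_points`, `n_above_threshold`,
#'   `method_tag = "hinge_grid"`, and `bootstrap_ci` (NULL until
#'   [bootstrap_fit()] fills it).
#' @export
#' @examples
#' p <- 1:9
#' e <- pmax(0, 16.3 * (p - 3.478))
#' fit_hinge(p, e)
fit_hinge <- function(plasma_pi, excreted, weights = NULL,
                      grid_resolution = 0.01, min_above = 3,
                      theta_max = Inf) {
  keep <- !is.na(plasma_pi) & !is.na(excreted)
  p <- as.numeric(plasma_pi[keep]); e <- as.numeric(excreted[keep])
  w <- if (is.null(weights)) rep(1, length(p)) else as.numeric(weights[keep])
  stopifnot(all(p >= 0), all(w >= 0), grid_resolution > 0, min_above >= 1)
  if (length(unique(p)) < min_above + 1) {
    pk_stop("phoskin_error_degenerate_fit",
            sprintf("need at least %d distinct plasma values", min_above + 1))
  }
  if (all(e * w == 0)) {
    pk_stop("phoskin_error_degenerate_fit",
            "all excretion values are zero: no titration signal")
  }

  sse_at <- function(theta) {
    above <- p > theta
    d <- p[above] - theta
    denom <- sum(w[above] * d^2)
    g <- if (denom > 0) max(0, sum(w[above] * e[above] * d) / denom) else 0
    resid_above <- e[above] - g * d
    list(sse = sum(w[above] * resid_above^2) + sum(w[!above] * e[!above]^2),
         g = g, n_above = sum(above))
  }

  grid <- seq(0, min(max(p), theta_max), by = grid_resolution)
  valid <- vapply(grid, function(th) sum(p > th) >= min_above, logical(1))
  if (!any(valid)) {
    pk_stop("phoskin_error_degenerate_fit",
            sprintf("no candidate threshold leaves >= %d points above it",
                    min_above))
  }
  grid <- grid[valid]
  sses <- vapply(grid, function(th) sse_at(th)$sse, numeric(1))
  i <- which.min(sses) # first minimum: ties break toward smaller theta

  # golden-section refinement within the bracketing grid cell
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- sse_at(x1)$sse; f2 <- sse_at(x2)$sse
  for (k in 1:60) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- sse_at(x1)$sse
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- sse_at(x2)$sse
    }
  }
  theta <- if (f1 <= f2) x1 else x2
  cand <- sse_at(theta)
  if (cand$sse > sses[i]) { # keep the grid point if refinement didn't help
    theta <- grid[i]
    cand <- sse_at(theta)
  }
  if (cand$n_above < min_above) {
    pk_stop("phoskin_error_degenerate_fit",
            sprintf("only %d points above the fitted threshold (< %d)",
                    cand$n_above, min_above))
  }
  if (cand$g <= 0) {
    pk_stop("phoskin_error_degenerate_fit",
            "fitted slope is not positive: no titration signal")
  }
  structure(list(gfr_est = cand$g,
                 threshold_est = theta,
                 tm_pi_est = cand$g * theta,
                 sse = cand$sse,
                 n_points = length(p),
                 n_above_threshold = cand$n_above,
                 bootstrap_ci = NULL,
                 method_tag = "hinge_grid"),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Threshold-linear titration fit (", x$method_tag, ")\n", sep = "")
  cat(sprintf("  GFR_Pi (slope):      %.2f mL/min\n", x$gfr_est))
  cat(sprintf("  TmPi/GFR (threshold): %.3f mmol/L\n", x$threshold_est))
  cat(sprintf("  TmPi:                %.1f umol/min\n", x$tm_pi_est))
  cat(sprintf("  points: %d (%d above threshold); SSE %.3g\n",
              x$n_points, x$n_above_threshold, x$sse))
  if (!is.null(x$bootstrap_ci)) {
    ci <- x$bootstrap_ci
    cat(sprintf("  %g%% bootstrap CIs (%d resamples, %d degenerate):\n",
                100 * attr(ci, "level"), attr(ci, "n_boot"),
                attr(ci, "n_degenerate")))
    for (par in rownames(ci)) {
      cat(sprintf("    %-13s [%.2f, %.2f]\n", par, ci[par, 1], ci[par, 2]))
    }
  }
  invisible(x)
}

#' Cohort titration fit on per-timepoint means
#'
#' The estimator used for cohort analyses. Collections are reduced to
#' per-timepoint cohort means of plasma Pi and excretion rate, and
#' [fit_hinge()] is applied to the mean curve — following the titration
#' trajectory the way the classical figure analysis does. Pooling raw
#' per-animal points instead is badly behaved here: once animals approach
#' their individual quasi-steady states, their points scatter along a
#' locus whose slope is set by the (negative) extrarenal balance, not by
#' GFR, which collapses the fitted slope.
#'
#' Two refinements:
#' \itemize{
#'   \item \emph{Straddling collections.} A collection whose plasma
#'     excursion brackets the fitted threshold has an interval-averaged
#'     excretion that cannot lie on the hinge (it is strictly above it),
#'     biasing both parameters low. After an initial fit, timepoints whose
#'     plasma range (estimated from the neighbouring means) straddles the
#'     threshold are dropped and the model refit (at most twice).
#'   \item \emph{Attenuation correction.} Plasma is measured with error,
#'     which attenuates the slope of a least-squares line (regression
#'     dilution). When the plasma assay CV is supplied, the fit is
#'     rescaled by the estimated reliability of the above-threshold mean
#'     plasma values: `g / lambda` and
#'     `theta_c = x_bar - (x_bar - theta) * lambda` with
#'     `lambda = (S_xx - sigma_x^2) / S_xx` clamped to `[0.5, 1]`.
#' }
#'
#' @param dataset A [pi_experiment()].
#' @param plasma_cv Known plasma Pi assay CV for the attenuation
#'   correction; `NULL` (default) disables it.
#' @param drop_straddling Drop threshold-straddling timepoints and refit.
#' @param grid_resolution,min_above Passed to [fit_hinge()].
#' @return A `titration_fit` (see [fit_hinge()]); `method_tag`
#'   `"hinge_grid/cohort_means"`.
#' @export
fit_titration <- function(dataset, plasma_cv = NULL, drop_straddling = TRUE,
                          grid_resolution = 0.01, min_above = 3) {
  stopifnot(inherits(dataset, "pi_experiment"))
  pts <- titration_points(dataset)
  fit_titration_points(pts, plasma_cv = plasma_cv,
                       drop_straddling = drop_straddling,
                       grid_resolution = grid_resolution,
                       min_above = min_above)
}

# the cohort estimator on a titration_points table (shared with bootstrap)
#' @noRd
fit_titration_points <- function(pts, plasma_cv = NULL,
                                 drop_straddling = TRUE,
                                 grid_resolution = 0.01, min_above = 3) {
  ag <- stats::aggregate(cbind(plasma_pi, excreted) ~ time_min, pts, mean)
  ag$n <- stats::aggregate(plasma_pi ~ time_min, pts, length)$plasma_pi
  ag <- ag[order(ag$plasma_pi), , drop = FALSE]
  p <- ag$plasma_pi; e <- ag$excreted
  # a timepoint excreting a substantial fraction of the maximum rate is
  # unambiguously above threshold; only the small interval-averaging
  # leakage of the threshold-straddling collection is tolerated below it
  theta_max <- suppressWarnings(min(p[e > 0.2 * max(e)]))
  fit <- fit_hinge(p, e, grid_resolution = grid_resolution,
                   min_above = min_above, theta_max = theta_max)
  keep <- rep(TRUE, length(p))
  if (isTRUE(drop_straddling)) {
    for (pass in 1:2) {
      th <- fit$threshold_est
      n <- length(p)
      lo <- c(p[1], (p[-n] + p[-1]) / 2)
      hi <- c((p[-n] + p[-1]) / 2, p[n])
      straddle <- lo < th & hi > th & keep
      if (!any(straddle)) break
      cand <- keep & !straddle
      if (sum(p[cand] > th) < min_above) break
      refit <- tryCatch(
        fit_hinge(p[cand], e[cand], grid_resolution = grid_resolution,
                  min_above = min_above, theta_max = theta_max),
        phoskin_error_degenerate_fit = function(err) NULL)
      if (is.null(refit)) break
      keep <- cand
      fit <- refit
    }
  }
  if (!is.null(plasma_cv)) {
    ab <- keep & p > fit$threshold_est
    xbar <- mean(p[ab])
    sxx <- mean((p[ab] - xbar)^2)
    sig2 <- mean((plasma_cv * p[ab])^2 / ag$n[ab])
    lambda <- min(1, max(0.5, (sxx - sig2) / sxx))
    g <- fit$gfr_est / lambda
    theta <- xbar - (xbar - fit$threshold_est) * lambda
    fit$gfr_est <- g
    fit$threshold_est <- theta
    fit$tm_pi_est <- g * theta
    fit$attenuation_lambda <- lambda
  }
  fit$n_points <- sum(keep)
  fit$method_tag <- "hinge_grid/cohort_means"
  fit
}

#' Direct transport-maximum estimate from saturated collections
#'
#' When the filtered load F exceeds the reabsorptive ceiling, reabsorption
#' is pinned at TmPi, so `mean(F - E)` over a window of saturated points
#' estimates TmPi directly.
#'
#' @param filtered Filtered loads F, µmol/min.
#' @param excreted Excretion rates E, µmol/min.
#' @param window Index or logical selector of the saturated points
#'   (default: all).
#' @param threshold_load Minimum filtered load for a point to count as
#'   saturated, µmol/min (e.g. a fitted `tm_pi_est`). Points below it
#'   raise an error. Default 0 (no check).
#' @return TmPi estimate, µmol/min (`method_tag` attribute
#'   `"plateau_window"`).
#' @export
plateau_tm <- function(filtered, excreted, window = seq_along(filtered),
                       threshold_load = 0) {
  f <- filtered[window]; e <- excreted[window]
  if (length(f) < 2 || any(is.na(f)) || any(is.na(e))) {
    pk_stop("phoskin_error_empty_window",
            "window must select at least 2 complete (F, E) points")
  }
  if (any(f < threshold_load)) {
    pk_stop("phoskin_error_below_threshold",
            "window contains filtered loads below the saturation threshold")
  }
  structure(mean(f - e), method_tag = "plateau_window")
}

#' Bootstrap the titration fit over animals
#'
#' Resamples animals with replacement, re-runs the cohort estimator
#' ([fit_titration()]) on each resample, and attaches percentile
#' confidence intervals for the slope, threshold and TmPi to the
#' full-data fit. Deterministic for a fixed seed. Resamples whose fit is
#' degenerate are counted and skipped; more than 20% degenerate raises an
#' error.
#'
#' @param dataset A [pi_experiment()] (>= 3 animals).
#' @param n_boot Number of bootstrap resamples. Default 500.
#' @param seed RNG seed.
#' @param level Confidence level. Default 0.95.
#' @param ci_type `"expanded"` (default) widens the percentile quantiles
#'   by the small-sample factor `sqrt(n/(n-1)) * t_(n-1) / z` (n = number
#'   of animals) to repair the well-known undercoverage of plain
#'   percentile intervals at small n; `"percentile"` gives the plain
#'   interval.
#' @param plasma_cv,drop_straddling Passed to [fit_titration()].
#' @param grid_resolution,min_above Passed to [fit_hinge()].
#' @return A `titration_fit` whose `bootstrap_ci` is a 3 x 2 matrix
#'   (rows `gfr_est`, `threshold_est`, `tm_pi_est`) with attributes
#'   `level`, `n_boot`, `n_degenerate`, and a `boot_samples` element
#'   holding the resampled estimates.
#' @export
bootstrap_fit <- function(dataset, n_boot = 500, seed = 1L, level = 0.95,
                          ci_type = c("expanded", "percentile"),
                          plasma_cv = NULL, drop_straddling = TRUE,
                          grid_resolution = 0.01, min_above = 3) {
  ci_type <- match.arg(ci_type)
  stopifnot(inherits(dataset, "pi_experiment"))
  pts <- titration_points(dataset)
  ids <- unique(pts$animal_id)
  if (length(ids) < 3) {
    pk_stop("phoskin_error_degenerate_fit",
            "bootstrap over animals needs at least 3 animals")
  }
  fit <- fit_titration_points(pts, plasma_cv = plasma_cv,
                              drop_straddling = drop_straddling,
                              grid_resolution = grid_resolution,
                              min_above = min_above)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("gfr_est", "threshold_est",
                                          "tm_pi_est")))
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    bp <- do.call(rbind, lapply(seq_along(take), function(k) {
      q <- pts[pts$animal_id == take[k], , drop = FALSE]
      q$animal_id <- sprintf("B%02d", k) # duplicates count as new animals
      q
    }))
    fb <- tryCatch(fit_titration_points(bp, plasma_cv = plasma_cv,
                                        drop_straddling = drop_straddling,
                                        grid_resolution = grid_resolution,
                                        min_above = min_above),
                   phoskin_error_degenerate_fit = function(e) NULL)
    if (is.null(fb)) {
      n_degenerate <- n_degenerate + 1L
    } else {
      draws[b, ] <- c(fb$gfr_est, fb$threshold_est, fb$tm_pi_est)
    }
  }
  if (n_degenerate > 0.2 * n_boot) {
    pk_stop("phoskin_error_bootstrap_degenerate",
            sprintf("%d of %d bootstrap refits degenerate (> 20%%)",
                    n_degenerate, n_boot))
  }
  alpha <- (1 - level) / 2
  if (ci_type == "expanded") {
    n <- length(ids)
    alpha <- stats::pnorm(-stats::qt(1 - alpha, n - 1) * sqrt(n / (n - 1)))
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  attr(ci, "level") <- level
  attr(ci, "ci_type") <- ci_type
  attr(ci, "n_boot") <- n_boot
  attr(ci, "n_degenerate") <- n_degenerate
  fit$bootstrap_ci <- ci
  fit$boot_samples <- draws
  fit
}

#' Per-animal (plasma Pi, excretion rate) pairs for titration fitting
#'
#' Pairs each urine collection's excretion rate with the plasma sample at
#' the collection midpoint; collections without a matching plasma sample
#' are dropped.
#'
#' @param dataset A [pi_experiment()].
#' @return data.frame with `animal_id`, `time_min` (midpoint),
#'   `plasma_pi`, `excreted`.
#' @export
titration_points <- function(dataset) {
  stopifnot(inherits(dataset, "pi_experiment"))
  ur <- dataset$urine
  pl <- dataset$plasma
  mid <- (ur$t_start_min + ur$t_end_min) / 2
  key <- function(id, t) paste(id, round(t, 6))
  p_map <- stats::setNames(pl$plasma_pi_mmol_l, key(pl$animal_id, pl$time_min))
  p <- unname(p_map[key(ur$animal_id, mid)])
  e <- excretion_rate(ur$urine_volume_ml, ur$urine_pi_mmol_l,
                      ur$t_start_min, ur$t_end_min)
  out <- data.frame(animal_id = ur$animal_id, time_min = mid,
                    plasma_pi = p, excreted = e)
  out[!is.na(out$plasma_pi), , drop = FALSE]
}
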