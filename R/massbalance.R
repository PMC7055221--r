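#' Mass-balance partition of the infused Pi load
#'
#' Partitions the input at each timepoint into renal excretion,
#' extracellular accumulation and a residual extrarenal elimination flux:
#' `X = I - E - dA/dt` where `A(t) = V(t) * P(t)` is the pool content and
#' `V(t) = v_d + expansion_rate * t` the expanding distribution volume.
#' The accumulation derivative uses central differences at interior
#' points and one-sided differences at the ends; the residual is defined
#' so the closure `I = E + accumulation + X` holds exactly at every point.
#' Cumulative columns are trapezoidal integrals of the instantaneous ones.
#'
#' A persistent positive residual while plasma is near steady state is
#' the evidence for a non-renal elimination route; note the residual also
#' absorbs any unmodelled endogenous Pi input, so `infusion` should
#' include known endogenous input where available.
#'
#' @param time Strictly increasing sample times, min (>= 3 points).
#' @param plasma_pi Plasma Pi at those times, mmol/L.
#' @param renal Renal excretion rate at those times, µmol/min.
#' @param infusion Pi input rate at those times, µmol/min (scalar or
#'   vector).
#' @param v_d Distribution volume at t = 0, mL.
#' @param expansion_rate Volume expansion rate, mL/min. Default 0.
#' @param smooth_window Width (in timepoints) of a centred moving average
#'   reported alongside the raw residual; 1 = no smoothing.
#' @return data.frame of class `mass_balance_series` with columns
#'   `time_min`, `infusion_in`, `renal_out`, `accumulation`, `extrarenal`,
#'   `extrarenal_smooth`, `cum_infusion`, `cum_renal`, `cum_accumulation`,
#'   `cum_extrarenal`; attribute `parity_time_min` (see [parity_time()]).
#' @export
extrarenal_series <- function(time, plasma_pi, renal, infusion,
                              v_d, expansion_rate = 0, smooth_window = 1) {
  n <- length(time)
  stopifnot(n == length(plasma_pi), n == length(renal), v_d > 0)
  if (n < 3) {
    pk_stop("phoskin_error_short_series",
            "mass balance needs at least 3 timepoints")
  }
  if (any(diff(time) <= 0)) {
    pk_stop("phoskin_error_time_order",
            "times must be strictly increasing with no duplicates")
  }
  infusion <- rep_len(infusion, n)
  amount <- (v_d + expansion_rate * time) * plasma_pi
  acc <- numeric(n)
  acc[1] <- (amount[2] - amount[1]) / (time[2] - time[1])
  acc[n] <- (amount[n] - amount[n - 1]) / (time[n] - time[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    acc[i] <- (amount[i + 1] - amount[i - 1]) / (time[i + 1] - time[i - 1])
  }
  x <- infusion - renal - acc
  xs <- if (smooth_window > 1) {
    stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2)
  } else x
  cum <- function(v) c(0, cumsum(diff(time) * (utils::head(v, -1) +
                                                 utils::tail(v, -1)) / 2))
  out <- data.frame(time_min = time, infusion_in = infusion,
                    renal_out = renal, accumulation = acc, extrarenal = x,
                    extrarenal_smooth = as.numeric(xs),
                    cum_infusion = cum(infusion), cum_renal = cum(renal),
                    cum_accumulation = cum(acc), cum_extrarenal = cum(x))
  class(out) <- c("mass_balance_series", "data.frame")
  attr(out, "parity_time_min") <- parity_time(out)
  out
}

#' Time at which renal elimination reaches parity with the extrarenal route
#'
#' Earliest time with `renal_out >= extrarenal`, linearly interpolated
#' between the bracketing timepoints.
#'
#' @param series A [extrarenal_series()] result (or any data.frame with
#'   `time_min`, `renal_out`, `extrarenal`).
#' @return Parity time in min, or `NA` if renal never reaches the
#'   extrarenal flux.
#' @export
parity_time <- function(series) {
  d <- series$renal_out - series$extrarenal
  if (d[1] >= 0) return(series$time_min[1])
  i <- which(d >= 0)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- series$time_min[i - 1]; t1 <- series$time_min[i]
  d0 <- d[i - 1]; d1 <- d[i]
  t0 + (0 - d0) / (d1 - d0) * (t1 - t0)
}
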