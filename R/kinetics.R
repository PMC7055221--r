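#' Urinary Pi excretion rate from a timed collection
#'
#' @param urine_volume_ml Collected volume, mL.
#' @param urine_pi_mmol_l Urinary Pi concentration, mmol/L.
#' @param t_start_min,t_end_min Collection interval bounds, min.
#' @return Excretion rate, µmol/min (mmol/L x mL / min = µmol/min).
#' @export
#' @examples
#' excretion_rate(6, 11.75, 0, 15)   # 4.7
#' excretion_rate(12, 93, 0, 15)     # 74.4
excretion_rate <- function(urine_volume_ml, urine_pi_mmol_l,
                           t_start_min, t_end_min) {
  dt <- t_end_min - t_start_min
  if (any(dt <= 0)) {
    pk_stop("phoskin_error_collection_order",
            "collection interval must have t_end > t_start")
  }
  urine_volume_ml * urine_pi_mmol_l / dt
}

#' Filtered load of Pi
#'
#' Rate at which Pi enters the nephrons: ultrafilterable plasma Pi times
#' the glomerular filtration rate.
#'
#' @param plasma_pi Plasma Pi, mmol/L.
#' @param gfr Glomerular filtration rate, mL/min.
#' @param f_uf Ultrafilterable fraction, in (0, 1].
#' @return Filtered load, µmol/min.
#' @export
filtered_load <- function(plasma_pi, gfr, f_uf = 1) {
  stopifnot(all(plasma_pi >= 0), all(gfr >= 0), all(f_uf >= 0))
  f_uf * gfr * plasma_pi
}

#' Fractional excretion of Pi
#'
#' `FePi = 100 * excreted / filtered` (%). Values above 100% indicate net
#' tubular secretion or data error and are returned unchanged (with a
#' warning), never clipped.
#'
#' @param excreted Urinary excretion rate E, µmol/min.
#' @param filtered Filtered load F, µmol/min (> 0).
#' @return FePi, percent.
#' @export
#' @examples
#' fractional_excretion(4.7, 33.1)    # 14.2
#' fractional_excretion(78.3, 127)    # 61.7
fractional_excretion <- function(excreted, filtered) {
  if (any(filtered == 0)) {
    pk_stop("phoskin_error_undefined_value",
            "fractional excretion is undefined when the filtered load is 0")
  }
  fe <- 100 * excreted / filtered
  if (any(fe > 100)) {
    pk_warn("phoskin_warning_net_secretion",
            "FePi > 100%: excretion exceeds filtered load (net secretion?)")
  }
  fe
}

#' Tubular Pi reabsorption rate
#'
#' `R = F - E`. Negative values indicate net secretion and are returned
#' with a warning, never clipped.
#'
#' @param filtered Filtered load F, µmol/min.
#' @param excreted Excretion rate E, µmol/min.
#' @return Reabsorption rate, µmol/min.
#' @export
reabsorption_rate <- function(filtered, excreted) {
  stopifnot(all(filtered >= 0), all(excreted >= 0))
  r <- filtered - excreted
  if (any(r < 0)) {
    pk_warn("phoskin_warning_net_secretion",
            "negative reabsorption: excretion exceeds filtered load")
  }
  r
}

#' Transport maximum per metabolic body weight
#'
#' Allometric normalization `TmPi / body_weight^0.75`, the standard scale
#' for comparing tubular transport maxima across species.
#'
#' @param tm_pi Transport maximum, µmol/min.
#' @param body_weight Body weight, kg.
#' @return µmol/min/kg^0.75.
#' @export
#' @examples
#' tm_per_metabolic_mass(56.7, 3.28)  # ~23.3
tm_per_metabolic_mass <- function(tm_pi, body_weight) {
  tm_pi / metabolic_weight(body_weight)
}

# midpoint time label for a collection; in "midpoint" mode the control
# (pre-infusion) interval is labelled 0
#' @noRd
time_labels <- function(t_start, t_end, mode = c("midpoint", "start")) {
  mode <- match.arg(mode)
  if (mode == "start") return(t_start)
  mid <- (t_start + t_end) / 2
  ifelse(mid < 0, 0, mid)
}

#' Per-timepoint renal Pi kinetics table
#'
#' Computes, for each collection timepoint, the cohort summary of urinary
#' excretion rate (E), filtered load (F), fractional excretion (FePi) and
#' tubular reabsorption (R): mean, SD (n-1 denominator) and per-cell N.
#' Missing measurements simply reduce the cell's N.
#'
#' Two aggregation modes for the ratio quantities:
#' \describe{
#'   \item{`mean_of_ratios`}{(default) FePi and R are computed per animal
#'     where both E and F exist, then averaged — the statistically
#'     preferable estimator for new analyses.}
#'   \item{`ratio_of_means`}{FePi = 100 x mean(E)/mean(F) and
#'     R = mean(F) - mean(E) from the cell means — the arithmetic used in
#'     classical printed kinetics tables.}
#' }
#'
#' @param dataset A [pi_experiment()].
#' @param gfr GFR used for the filtered load, mL/min (a fitted or supplied
#'   scalar).
#' @param mode Aggregation mode for FePi and R.
#' @param label_mode Timepoint labelling: interval `"midpoint"` (control
#'   interval labelled 0) or interval `"start"`.
#' @return A data.frame of class `kinetics_table`, one row per timepoint,
#'   with columns `time_min`, then `<q>_mean`, `<q>_sd`, `<q>_n` for
#'   `filtered`, `excreted`, `fe_pi`, `reabsorbed`; attributes `gfr_used`,
#'   `aggregation_mode`, `f_uf`.
#' @export
build_kinetics_table <- function(dataset, gfr,
                                 mode = c("mean_of_ratios", "ratio_of_means"),
                                 label_mode = c("midpoint", "start")) {
  stopifnot(inherits(dataset, "pi_experiment"), gfr > 0)
  mode <- match.arg(mode)
  label_mode <- match.arg(label_mode)
  f_uf <- dataset$ultrafilterable_fraction

  ur <- dataset$urine
  ur$time_min <- time_labels(ur$t_start_min, ur$t_end_min, label_mode)
  ur$excreted <- excretion_rate(ur$urine_volume_ml, ur$urine_pi_mmol_l,
                                ur$t_start_min, ur$t_end_min)
  ur$midpoint <- (ur$t_start_min + ur$t_end_min) / 2

  pl <- dataset$plasma
  pl$filtered <- filtered_load(pl$plasma_pi_mmol_l, gfr, f_uf)

  # pair E with the plasma sample at the collection midpoint
  key <- function(id, t) paste(id, round(t, 6))
  pl_map <- stats::setNames(pl$filtered, key(pl$animal_id, pl$time_min))
  ur$filtered <- unname(pl_map[key(ur$animal_id, ur$midpoint)])

  pl$time_label <- ur$time_min[match(key(pl$animal_id, pl$time_min),
                                     key(ur$animal_id, ur$midpoint))]
  unmatched <- is.na(pl$time_label)
  pl$time_label[unmatched] <- pl$time_min[unmatched]

  cell <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x))
  }
  labels <- sort(unique(c(ur$time_min, pl$time_label)))
  rows <- lapply(labels, function(tl) {
    e <- ur$excreted[ur$time_min == tl]
    f <- pl$filtered[pl$time_label == tl]
    if (length(e) == 0 && length(f) == 0) return(NULL)
    ec <- cell(e); fc <- cell(f)
    both_f <- ur$filtered[ur$time_min == tl]
    both_e <- ur$excreted[ur$time_min == tl]
    ok <- !is.na(both_f) & !is.na(both_e)
    if (mode == "mean_of_ratios") {
      fec <- cell(ifelse(both_f[ok] > 0, 100 * both_e[ok] / both_f[ok],
                         NA_real_))
      rc <- cell(both_f[ok] - both_e[ok])
    } else {
      fe <- if (fc[["n"]] > 0 && ec[["n"]] > 0 && fc[["mean"]] > 0)
        100 * ec[["mean"]] / fc[["mean"]] else NA_real_
      rr <- if (fc[["n"]] > 0 && ec[["n"]] > 0) fc[["mean"]] - ec[["mean"]]
        else NA_real_
      nn <- min(fc[["n"]], ec[["n"]])
      fec <- c(mean = fe, sd = NA_real_, n = nn)
      rc <- c(mean = rr, sd = NA_real_, n = nn)
    }
    data.frame(time_min = tl,
               filtered_mean = fc[["mean"]], filtered_sd = fc[["sd"]],
               filtered_n = fc[["n"]],
               excreted_mean = ec[["mean"]], excreted_sd = ec[["sd"]],
               excreted_n = ec[["n"]],
               fe_pi_mean = fec[["mean"]], fe_pi_sd = fec[["sd"]],
               fe_pi_n = fec[["n"]],
               reabsorbed_mean = rc[["mean"]], reabsorbed_sd = rc[["sd"]],
               reabsorbed_n = rc[["n"]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    pk_stop("phoskin_error_empty_table", "no timepoints with any data")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, gfr_used = gfr, aggregation_mode = mode, f_uf = f_uf,
            class = c("kinetics_table", "data.frame"))
}
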