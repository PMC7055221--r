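#' Configuration for a full analysis run
#'
#' @param data_dir Directory with the experiment CSVs and protocol file
#'   (see [read_experiment()]).
#' @param out_dir Output directory for `table.csv`, `fit.json`,
#'   `balance.csv` and `report.txt`.
#' @param gfr_mode `"fit"` to estimate GFR_Pi from the titration fit, or
#'   a positive number to fix it.
#' @param aggregation_mode Passed to [build_kinetics_table()].
#' @param grid_resolution,min_above,n_boot,seed Titration fit options
#'   (see [fit_hinge()], [bootstrap_fit()]).
#' @param plasma_cv,drop_straddling Cohort-estimator options (see
#'   [fit_titration()]).
#' @param v_d_per_kg Distribution volume per kg for the mass balance,
#'   mL/kg.
#' @param expansion_rate Volume expansion rate, mL/min; `NULL` = the
#'   protocol's infusate volumetric rate.
#' @param include_expansion Also report the mass balance with the
#'   expansion term switched off (the volume held at its t = 0 value) for
#'   comparison. Default TRUE.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(data_dir, out_dir,
                            gfr_mode = "fit",
                            aggregation_mode = "mean_of_ratios",
                            grid_resolution = 0.01, min_above = 3,
                            plasma_cv = NULL, drop_straddling = TRUE,
                            n_boot = 500, seed = 1L,
                            v_d_per_kg = 200, expansion_rate = NULL,
                            include_expansion = TRUE) {
  if (!(identical(gfr_mode, "fit") ||
        (is.numeric(gfr_mode) && gfr_mode > 0))) {
    pk_stop("phoskin_error_invalid_config",
            "gfr_mode must be \"fit\" or a positive number")
  }
  if (!aggregation_mode %in% c("mean_of_ratios", "ratio_of_means")) {
    pk_stop("phoskin_error_invalid_config",
            "aggregation_mode must be mean_of_ratios or ratio_of_means")
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full excretion-kinetics analysis
#'
#' Reads the dataset, (optionally) fits the titration model with
#' bootstrap uncertainty, builds the per-timepoint kinetics table, runs
#' the cohort-mean mass balance, and writes `table.csv`, `fit.json`,
#' `balance.csv` and a human-readable `report.txt` that states every
#' defaulted assumption. Deterministic for a fixed config and seed.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with `dataset`, `fit`, `table`, `balance`,
#'   `paths`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dataset <- read_experiment(config$data_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  fit <- NULL
  if (identical(config$gfr_mode, "fit")) {
    fit <- bootstrap_fit(dataset, n_boot = config$n_boot, seed = config$seed,
                         plasma_cv = config$plasma_cv,
                         drop_straddling = config$drop_straddling,
                         grid_resolution = config$grid_resolution,
                         min_above = config$min_above)
    gfr <- fit$gfr_est
  } else {
    gfr <- config$gfr_mode
  }

  tab <- build_kinetics_table(dataset, gfr, mode = config$aggregation_mode)

  # cohort-mean mass balance on the plasma/excretion timepoint means
  exp_rate <- config$expansion_rate %||% infusate_flow(dataset$protocol)
  v_d <- config$v_d_per_kg * mean(dataset$animals$body_weight_kg)
  pl_mean <- stats::aggregate(plasma_pi_mmol_l ~ time_min, dataset$plasma,
                              mean)
  pts <- titration_points(dataset)
  e_mean <- stats::aggregate(excreted ~ time_min, pts, mean)
  mb <- merge(pl_mean, e_mean, by = "time_min")
  mb <- mb[order(mb$time_min), ]
  infus <- ifelse(mb$time_min >= 0 &
                    mb$time_min < dataset$protocol$infusion_duration,
                  dataset$protocol$pi_infusion_rate, 0)
  balance <- extrarenal_series(mb$time_min, mb$plasma_pi_mmol_l, mb$excreted,
                               infus, v_d = v_d, expansion_rate = exp_rate,
                               smooth_window = 3)
  balance_static <- if (isTRUE(config$include_expansion)) {
    extrarenal_series(mb$time_min, mb$plasma_pi_mmol_l, mb$excreted, infus,
                      v_d = v_d, expansion_rate = 0, smooth_window = 3)
  }

  paths <- c(table = file.path(config$out_dir, "table.csv"),
             fit = file.path(config$out_dir, "fit.json"),
             balance = file.path(config$out_dir, "balance.csv"),
             report = file.path(config$out_dir, "report.txt"))
  utils::write.csv(as.data.frame(tab), paths["table"], row.names = FALSE)
  utils::write.csv(as.data.frame(balance), paths["balance"],
                   row.names = FALSE)
  if (!is.null(fit)) {
    fj <- fit[c("gfr_est", "threshold_est", "tm_pi_est", "sse", "n_points",
                "n_above_threshold", "method_tag")]
    ci <- fit$bootstrap_ci
    fj$bootstrap_ci <- list(level = attr(ci, "level"),
                            n_boot = attr(ci, "n_boot"),
                            n_degenerate = attr(ci, "n_degenerate"),
                            gfr_est = unname(ci["gfr_est", ]),
                            threshold_est = unname(ci["threshold_est", ]),
                            tm_pi_est = unname(ci["tm_pi_est", ]))
    fj$seed <- config$seed
    jsonlite::write_json(fj, paths["fit"], auto_unbox = TRUE, digits = NA)
  }

  bw <- mean(dataset$animals$body_weight_kg)
  fe <- tab$fe_pi_mean[!is.na(tab$fe_pi_mean)]
  pt <- attr(balance, "parity_time_min")
  lines <- c(
    "Renal phosphate excretion kinetics: analysis report",
    sprintf("animals: %d; mean body weight %.2f kg", nrow(dataset$animals),
            bw),
    sprintf("GFR_Pi: %.2f mL/min (%s)", gfr,
            if (is.null(fit)) "fixed by user" else "titration-fit slope"),
    if (!is.null(fit)) sprintf(
      "TmPi/GFR: %.2f mmol/L; TmPi: %.1f umol/min (%.1f umol/min/kg^0.75)",
      fit$threshold_est, fit$tm_pi_est,
      tm_per_metabolic_mass(fit$tm_pi_est, bw)),
    if (!is.null(fit)) sprintf(
      "  95%% bootstrap CIs: slope [%.2f, %.2f], threshold [%.2f, %.2f], TmPi [%.1f, %.1f]; seed %d",
      fit$bootstrap_ci["gfr_est", 1], fit$bootstrap_ci["gfr_est", 2],
      fit$bootstrap_ci["threshold_est", 1],
      fit$bootstrap_ci["threshold_est", 2],
      fit$bootstrap_ci["tm_pi_est", 1], fit$bootstrap_ci["tm_pi_est", 2],
      as.integer(config$seed)),
    sprintf("FePi range: %.1f%% to %.1f%%", min(fe), max(fe)),
    sprintf("parity time (renal >= extrarenal flux): %s",
            if (is.na(pt)) "not reached" else sprintf("%.1f min", pt)),
    "assumptions:",
    sprintf("  ultrafilterable fraction f_uf = %g",
            dataset$ultrafilterable_fraction),
    sprintf("  distribution volume = %g mL/kg x %.2f kg = %.0f mL",
            config$v_d_per_kg, bw, v_d),
    sprintf("  volume expansion rate = %.2f mL/min", exp_rate),
    sprintf("  aggregation mode = %s", config$aggregation_mode),
    if (!is.null(balance_static)) sprintf(
      "  without-expansion parity time: %s",
      if (is.na(attr(balance_static, "parity_time_min"))) "not reached"
      else sprintf("%.1f min", attr(balance_static, "parity_time_min")))
  )
  writeLines(lines, paths["report"])

  invisible(list(dataset = dataset, fit = fit, table = tab,
                 balance = balance, balance_static = balance_static,
                 paths = paths))
}
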