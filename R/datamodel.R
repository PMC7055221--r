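#' Infusion protocol for a phosphate-loading experiment
#'
#' Describes the intravenous sodium phosphate infusion and the urine
#' sampling schedule. Time zero is the start of the phosphate infusion; a
#' control urine collection occupies the `pre_infusion_control_interval`
#' minutes immediately before it.
#'
#' @param pi_infusion_rate Pi infusion rate, µmol/min. Default 120.
#' @param infusate_conc Infusate Pi concentration, mmol/L. Default 100
#'   (0.1 M sodium phosphate); together with the infusion rate this fixes
#'   the volumetric infusion rate `pi_infusion_rate / infusate_conc`
#'   (mL/min, 1.2 at the defaults) which drives extracellular volume
#'   expansion.
#' @param infusion_start Start of infusion, min. Defines t = 0.
#' @param infusion_duration Duration of the loading period, min. Default
#'   105 (seven 15-minute collections with plasma midpoints 7.5–97.5 min).
#' @param collection_interval Length of each timed urine collection, min.
#' @param pre_infusion_control_interval Length of the control collection
#'   preceding the infusion, min.
#' @return An object of class `infusion_protocol` (named list).
#' @export
#' @examples
#' p <- infusion_protocol()
#' infusate_flow(p)  # 1.2 mL/min
infusion_protocol <- function(pi_infusion_rate = 120,
                              infusate_conc = 100,
                              infusion_start = 0,
                              infusion_duration = 105,
                              collection_interval = 15,
                              pre_infusion_control_interval = 15) {
  p <- list(
    pi_infusion_rate = as.numeric(pi_infusion_rate),
    infusate_conc = as.numeric(infusate_conc),
    infusion_start = as.numeric(infusion_start),
    infusion_duration = as.numeric(infusion_duration),
    collection_interval = as.numeric(collection_interval),
    pre_infusion_control_interval = as.numeric(pre_infusion_control_interval)
  )
  pos <- c("pi_infusion_rate", "infusate_conc", "infusion_duration",
           "collection_interval", "pre_infusion_control_interval")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      pk_stop("phoskin_error_invalid_protocol",
              sprintf("protocol field '%s' must be strictly positive", f))
    }
  }
  structure(p, class = "infusion_protocol")
}

#' Volumetric infusate flow implied by a protocol
#'
#' @param protocol An [infusion_protocol()].
#' @return Infusate volumetric rate, mL/min (rate / concentration).
#' @export
infusate_flow <- function(protocol) {
  protocol$pi_infusion_rate / protocol$infusate_conc
}

#' Metabolic body weight
#'
#' Allometric normalizer `body_weight^0.75` (kg^0.75) used to scale
#' transport maxima across species.
#'
#' @param body_weight Body weight, kg (> 0).
#' @return kg^0.75.
#' @export
metabolic_weight <- function(body_weight) {
  stopifnot(all(body_weight > 0))
  body_weight^0.75
}

#' Assemble a phosphate-loading experiment dataset
#'
#' Bundles the infusion protocol with per-animal records, plasma Pi samples
#' (taken at collection-interval midpoints) and timed urine collections,
#' and validates cross-references and invariants.
#'
#' @param protocol An [infusion_protocol()].
#' @param animals data.frame with columns `animal_id`, `body_weight_kg`.
#' @param plasma data.frame with columns `animal_id`, `time_min`,
#'   `plasma_pi_mmol_l`.
#' @param urine data.frame with columns `animal_id`, `t_start_min`,
#'   `t_end_min`, `urine_volume_ml`, `urine_pi_mmol_l`.
#' @param ultrafilterable_fraction Fraction of plasma Pi that is
#'   ultrafilterable at the glomerulus, in (0, 1]. Default 1 (no
#'   correction); 0.90–0.95 is physiologically typical.
#' @return An object of class `pi_experiment`: a list with elements
#'   `protocol`, `animals`, `plasma`, `urine`, `ultrafilterable_fraction`.
#'   `animals` gains a derived `metabolic_weight_kg075` column.
#' @export
pi_experiment <- function(protocol, animals, plasma, urine,
                          ultrafilterable_fraction = 1.0) {
  stopifnot(inherits(protocol, "infusion_protocol"))
  animals <- as.data.frame(animals)
  plasma <- as.data.frame(plasma)
  urine <- as.data.frame(urine)
  rownames(animals) <- rownames(plasma) <- rownames(urine) <- NULL
  animals$animal_id <- as.character(animals$animal_id)
  plasma$animal_id <- as.character(plasma$animal_id)
  urine$animal_id <- as.character(urine$animal_id)
  pk_require_cols(animals, c("animal_id", "body_weight_kg"), "animals")
  pk_require_cols(plasma, c("animal_id", "time_min", "plasma_pi_mmol_l"),
                  "plasma")
  pk_require_cols(urine, c("animal_id", "t_start_min", "t_end_min",
                           "urine_volume_ml", "urine_pi_mmol_l"), "urine")

  if (anyDuplicated(animals$animal_id)) {
    pk_stop("phoskin_error_duplicate_animal", "duplicated animal_id in animals")
  }
  if (any(!is.finite(animals$body_weight_kg) | animals$body_weight_kg <= 0)) {
    pk_stop("phoskin_error_invalid_value", "body_weight_kg must be > 0")
  }
  animals$metabolic_weight_kg075 <- metabolic_weight(animals$body_weight_kg)

  for (tab in c("plasma", "urine")) {
    ids <- get(tab)$animal_id
    unknown <- setdiff(unique(ids), animals$animal_id)
    if (length(unknown)) {
      pk_stop("phoskin_error_unknown_animal",
              sprintf("'%s' references unknown animal_id: %s",
                      tab, paste(unknown, collapse = ", ")))
    }
  }
  if (any(plasma$plasma_pi_mmol_l < 0, na.rm = TRUE)) {
    pk_stop("phoskin_error_invalid_value", "plasma_pi_mmol_l must be >= 0")
  }
  bad <- which(urine$t_end_min <= urine$t_start_min)
  if (length(bad)) {
    pk_stop("phoskin_error_collection_order",
            sprintf("urine row(s) %s have t_end <= t_start",
                    paste(bad, collapse = ", ")))
  }
  if (any(urine$urine_volume_ml < 0 | urine$urine_pi_mmol_l < 0, na.rm = TRUE)) {
    pk_stop("phoskin_error_invalid_value",
            "urine volume and concentration must be >= 0")
  }
  # collections for one animal must not overlap
  for (id in unique(urine$animal_id)) {
    u <- urine[urine$animal_id == id, , drop = FALSE]
    u <- u[order(u$t_start_min), , drop = FALSE]
    if (nrow(u) > 1 && any(u$t_start_min[-1] < u$t_end_min[-nrow(u)] - 1e-9)) {
      pk_stop("phoskin_error_overlapping_collections",
              sprintf("overlapping urine collections for animal '%s'", id))
    }
  }
  if (!(ultrafilterable_fraction > 0 && ultrafilterable_fraction <= 1)) {
    pk_stop("phoskin_error_invalid_value",
            "ultrafilterable_fraction must be in (0, 1]")
  }

  # plasma samples should sit at the midpoint of a collection when one exists
  mids <- (urine$t_start_min + urine$t_end_min) / 2
  for (i in seq_len(nrow(plasma))) {
    same <- abs(mids - plasma$time_min[i]) < 1e-6 &
      urine$animal_id == plasma$animal_id[i]
    if (nrow(urine) > 0 && any(urine$animal_id == plasma$animal_id[i]) &&
        !any(same)) {
      pk_warn("phoskin_warning_unmatched_plasma",
              sprintf(
                "plasma sample (animal '%s', t = %g min) matches no urine collection midpoint; retained",
                plasma$animal_id[i], plasma$time_min[i]))
    }
  }

  structure(list(protocol = protocol,
                 animals = animals,
                 plasma = plasma,
                 urine = urine,
                 ultrafilterable_fraction = ultrafilterable_fraction),
            class = "pi_experiment")
}

#' @export
print.pi_experiment <- function(x, ...) {
  cat("Phosphate-loading experiment dataset\n")
  cat(sprintf("  animals: %d (mean body weight %.2f kg)\n",
              nrow(x$animals), mean(x$animals$body_weight_kg)))
  cat(sprintf("  plasma samples: %d; urine collections: %d\n",
              nrow(x$plasma), nrow(x$urine)))
  cat(sprintf("  infusion: %g umol/min for %g min; collections every %g min\n",
              x$protocol$pi_infusion_rate, x$protocol$infusion_duration,
              x$protocol$collection_interval))
  cat(sprintf("  ultrafilterable fraction: %g\n", x$ultrafilterable_fraction))
  invisible(x)
}

protocol_fields <- c("pi_infusion_rate", "infusate_conc", "infusion_start",
                     "infusion_duration", "collection_interval",
                     "pre_infusion_control_interval")

#' Read a phosphate-loading experiment from CSV tables and a protocol file
#'
#' Expects `animals.csv`, `plasma.csv` and `urine.csv` (comma-separated,
#' UTF-8, "." decimal, one header row, empty cells for missing values) plus
#' a JSON or YAML protocol file carrying the [infusion_protocol()] fields
#' and optionally `ultrafilterable_fraction`. All quantities must already be
#' in the canonical units named by the column headers (min, mL, mmol/L, kg).
#'
#' @param dir Directory containing `animals.csv`, `plasma.csv`, `urine.csv`
#'   and `protocol.json` or `protocol.yaml`. Alternatively pass explicit
#'   `paths`.
#' @param paths Optional named list/character vector with elements
#'   `animals`, `plasma`, `urine` overriding the defaults under `dir`.
#' @param protocol_path Optional explicit protocol file path.
#' @return A validated [pi_experiment()].
#' @export
read_experiment <- function(dir = NULL, paths = NULL, protocol_path = NULL) {
  loc <- function(name, default) {
    if (!is.null(paths) && !is.null(paths[[name]])) return(paths[[name]])
    file.path(dir, default)
  }
  f_animals <- loc("animals", "animals.csv")
  f_plasma <- loc("plasma", "plasma.csv")
  f_urine <- loc("urine", "urine.csv")
  if (is.null(protocol_path)) {
    cand <- file.path(dir, c("protocol.json", "protocol.yaml", "protocol.yml"))
    protocol_path <- cand[file.exists(cand)][1]
  }
  for (f in c(f_animals, f_plasma, f_urine, protocol_path)) {
    if (is.na(f) || !file.exists(f)) {
      pk_stop("phoskin_error_missing_file",
              sprintf("required input file not found: %s",
                      if (is.na(f)) "protocol.{json,yaml}" else f))
    }
  }

  pr <- if (grepl("\\.json$", protocol_path)) {
    jsonlite::read_json(protocol_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(protocol_path)
  }
  f_uf <- as.numeric(pr$ultrafilterable_fraction %||% 1.0)
  pr <- pr[intersect(names(pr), protocol_fields)]
  protocol <- do.call(infusion_protocol, pr)

  animals <- utils::read.csv(f_animals, stringsAsFactors = FALSE)
  plasma <- utils::read.csv(f_plasma, stringsAsFactors = FALSE)
  urine <- utils::read.csv(f_urine, stringsAsFactors = FALSE)
  pk_require_cols(animals, c("animal_id", "body_weight_kg"), f_animals)
  pk_require_cols(plasma, c("animal_id", "time_min", "plasma_pi_mmol_l"),
                  f_plasma)
  pk_require_cols(urine, c("animal_id", "t_start_min", "t_end_min",
                           "urine_volume_ml", "urine_pi_mmol_l"), f_urine)
  animals$animal_id <- as.character(animals$animal_id)
  plasma$animal_id <- as.character(plasma$animal_id)
  urine$animal_id <- as.character(urine$animal_id)
  animals$body_weight_kg <- pk_numeric(animals$body_weight_kg,
                                       "body_weight_kg", f_animals)
  for (col in c("time_min", "plasma_pi_mmol_l")) {
    plasma[[col]] <- pk_numeric(plasma[[col]], col, f_plasma)
  }
  for (col in c("t_start_min", "t_end_min", "urine_volume_ml",
                "urine_pi_mmol_l")) {
    urine[[col]] <- pk_numeric(urine[[col]], col, f_urine)
  }

  pi_experiment(protocol, animals, plasma, urine,
                ultrafilterable_fraction = f_uf)
}

#' Write a phosphate-loading experiment dataset to CSV tables
#'
#' Inverse of [read_experiment()]: writes `animals.csv`, `plasma.csv`,
#' `urine.csv` and `protocol.json` such that reading them back reproduces
#' the dataset field-for-field.
#'
#' @param dataset A [pi_experiment()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_experiment <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "pi_experiment"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    pk_stop("phoskin_error_unwritable", sprintf("cannot create '%s'", out_dir))
  }
  paths <- c(animals = file.path(out_dir, "animals.csv"),
             plasma = file.path(out_dir, "plasma.csv"),
             urine = file.path(out_dir, "urine.csv"),
             protocol = file.path(out_dir, "protocol.json"))
  # 17 significant digits so doubles survive the text round-trip exactly
  fmt <- function(df) {
    df[] <- lapply(df, function(x) {
      if (!is.numeric(x)) return(x)
      out <- vapply(x, function(v) {
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
      }, character(1))
      out
    })
    df
  }
  an <- fmt(dataset$animals[, c("animal_id", "body_weight_kg")])
  utils::write.csv(an, paths["animals"], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(dataset$plasma[, c("animal_id", "time_min",
                                          "plasma_pi_mmol_l")]),
                   paths["plasma"], row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(dataset$urine[, c("animal_id", "t_start_min",
                                         "t_end_min", "urine_volume_ml",
                                         "urine_pi_mmol_l")]),
                   paths["urine"], row.names = FALSE, quote = FALSE)
  pr <- unclass(dataset$protocol)
  pr$ultrafilterable_fraction <- dataset$ultrafilterable_fraction
  jsonlite::write_json(pr, paths["protocol"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
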