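#' @keywords internal
#' @noRd
pk_stop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "phoskin_error")))
}

#' @keywords internal
#' @noRd
pk_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "phoskin_warning")))
}

# numeric column coercion with a named error identifying file and row
#' @noRd
pk_numeric <- function(x, col, file) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad)) {
    pk_stop("phoskin_error_bad_number",
            sprintf("unparseable number in '%s', column '%s', row(s) %s",
                    file, col, paste(bad, collapse = ", ")))
  }
  out
}

#' @noRd
pk_require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    pk_stop("phoskin_error_missing_column",
            sprintf("file '%s' is missing required column(s): %s",
                    file, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
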