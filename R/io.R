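# Long-format dataset I/O.
#
# The common currency of fitting, simulation and evaluation is a
# NONMEM-style long table:
#   observations: id, time_min, matrix {plasma|brain_ecf}, conc_ng_ml, bql {0|1}
#   dosing:       id, time_min, dose_mg_kg, route

.OBS_COLS <- c("id", "time_min", "matrix", "conc_ng_ml", "bql")
.DOSE_COLS <- c("id", "time_min", "dose_mg_kg", "route")

#' Validate an observation table against the dataset schema
#'
#' @param df data frame to check.
#' @return invisibly TRUE; errors describe every violated rule.
#' @export
validate_study_schema <- function(df) {
  miss <- setdiff(.OBS_COLS, names(df))
  if (length(miss))
    stop("missing observation columns: ", paste(miss, collapse = ", "))
  errs <- character(0)
  if (!all(df$matrix %in% c("plasma", "brain_ecf")))
    errs <- c(errs, "matrix must be 'plasma' or 'brain_ecf'")
  if (!all(df$bql %in% c(0L, 1L)))
    errs <- c(errs, "bql must be 0 or 1")
  if (any(!is.finite(df$time_min) | df$time_min < 0))
    errs <- c(errs, "time_min must be finite and non-negative")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  invisible(TRUE)
}

#' Read / write study observation tables
#'
#' @param path CSV path.
#' @return data frame conforming to the observation schema.
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_schema(df)
  df
}

#' @rdname read_study_csv
#' @param df observation data frame.
#' @export
write_study_csv <- function(df, path) {
  validate_study_schema(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write dosing tables
#'
#' @param path CSV path.
#' @export
read_dosing_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.DOSE_COLS, names(df))
  if (length(miss))
    stop("missing dosing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_dosing_csv
#' @param df dosing data frame.
#' @export
write_dosing_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
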