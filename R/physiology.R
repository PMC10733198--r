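# Mouse CNS physiology registry
#
# The registry stores, for every physiological parameter, the literature
# values that were collected, the aggregation rule that produced the final
# value (mean, median, a single source, or a derivation from other
# parameters), and the final value itself in its reporting unit.
# Downstream code consumes a canonicalized named list in {ml, ng, min,
# cm, cm2} units.

#' Aggregate literature values of a physiological parameter
#'
#' When several literature values exist for one parameter the final value
#' is their mean (or, for total brain volume, their median).
#'
#' @param values non-empty numeric vector of positive literature values.
#' @param method `"mean"` or `"median"`.
#' @return the aggregated value.
#' @examples
#' aggregate_parameter(c(18.78, 20.74), "mean")   # BBB surface, 19.76 cm2
#' aggregate_parameter(c(150, 303, 350, 360, 360, 360, 495), "median")
#' @export
aggregate_parameter <- function(values, method = c("mean", "median")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all literature values must be positive and finite")
  switch(method, mean = mean(values), median = stats::median(values))
}

#' CSF bulk-flow estimate from turnover
#'
#' CSF flow (ml/min) computed as CSF volume times daily turnover:
#' `volume_ml * turnover_per_day / (24 * 60)`.
#'
#' @param csf_volume_ml CSF volume in ml (default 0.040).
#' @param turnover_per_day turnover rate per day (default 13).
#' @export
csf_flow_from_turnover <- function(csf_volume_ml = 0.040,
                                   turnover_per_day = 13) {
  csf_volume_ml * turnover_per_day / (24 * 60)
}

#' Brain-cell membrane surface area under the monodisperse-sphere model
#'
#' All brain cells are modelled as identical spheres that jointly hold the
#' intracellular fluid volume; the total membrane area is then
#' `N * (36*pi)^(1/3) * (V_ICF/N)^(2/3)` with `V_ICF` in cm3.
#'
#' @param n_cells number of brain cells.
#' @param v_icf_ml intracellular fluid volume in ml (= cm3).
#' @return surface area in cm2.
#' @export
cell_membrane_surface <- function(n_cells, v_icf_ml) {
  stopifnot(n_cells > 0, v_icf_ml > 0)
  n_cells * (36 * pi)^(1 / 3) * (v_icf_ml / n_cells)^(2 / 3)
}

.phys_unit_to_canonical <- function(value, unit) {
  switch(unit,
    "ul"     = value / 1000,      # -> ml
    "ml"     = value,
    "ml/min" = value,
    "cm2"    = value,
    "um"     = value * 1e-4,      # -> cm
    "unitless" = value,
    "pH"     = value,
    "count"  = value,
    "g"      = value,
    stop("unknown unit: ", unit)
  )
}

#' Apply derivation rules to a physiology registry
#'
#' Fills every parameter whose `aggregation` is `"derived"` from its
#' prerequisites: intracellular fluid volume is 80% of total brain volume,
#' total lysosomal volume is 1.25% of intracellular volume, the BCSFB
#' surface is 50% of the BBB surface, and the cell-membrane surface
#' follows [cell_membrane_surface()].
#'
#' @param reg a `cns_physiology` object (possibly with derived slots empty).
#' @return the registry with derived final values populated.
#' @export
derive_dependent_parameters <- function(reg) {
  stopifnot(inherits(reg, "cns_physiology"))
  p <- reg$parameters
  need <- function(nm) {
    fv <- p[[nm]]$final_value
    if (is.null(fv) || !is.finite(fv))
      stop("missing prerequisite parameter: ", nm)
    fv
  }
  rules <- list(
    V_ICF       = function() 0.8 * need("V_brain_total"),
    V_LYS_total = function() 0.0125 * need("V_ICF"),
    SA_BCSFB    = function() 0.5 * need("SA_BBB"),
    SA_BCM      = function() cell_membrane_surface(need("N_cells"),
                                                   need("V_ICF") / 1000)
  )
  for (nm in names(rules)) {
    if (!is.null(p[[nm]]) && identical(p[[nm]]$aggregation, "derived"))
      p[[nm]]$final_value <- rules[[nm]]()
  }
  reg$parameters <- p
  reg$values <- .phys_canonical_values(p)
  reg
}

.phys_canonical_values <- function(p) {
  vals <- lapply(p, function(z) .phys_unit_to_canonical(z$final_value, z$unit))
  names(vals) <- names(p)
  vals
}

#' Load a physiology registry from a structured-text file
#'
#' The JSON file stores one record per parameter: literature values,
#' units, aggregation rule and (for `single`/`derived` entries) the
#' adopted final value.  Aggregated entries are recomputed from their
#' literature values on load; derived entries are recomputed from their
#' prerequisites.
#'
#' @param path JSON file path.
#' @return object of class `cns_physiology`.
#' @export
read_physiology <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pars <- raw$parameters
  p <- lapply(pars, function(z) {
    z$literature_values <- as.numeric(unlist(z$literature_values))
    agg <- z$aggregation
    if (agg %in% c("mean", "median")) {
      z$final_value <- aggregate_parameter(z$literature_values, agg)
    } else if (agg == "single") {
      z$final_value <- as.numeric(z$final_value)
    } else if (agg == "derived") {
      z$final_value <- if (is.null(z$final_value)) NA_real_ else as.numeric(z$final_value)
    } else stop("unknown aggregation rule: ", agg)
    z
  })
  names(p) <- vapply(pars, `[[`, character(1), "name")
  reg <- structure(list(species = raw$species, parameters = p, values = NULL),
                   class = "cns_physiology")
  derive_dependent_parameters(reg)
}

#' Write a physiology registry to JSON
#'
#' Round-trips bit-exactly through [read_physiology()] (final values are
#' serialized at full precision and recomputation is deterministic).
#'
#' @param reg `cns_physiology` object.
#' @param path output path.
#' @export
write_physiology <- function(reg, path) {
  stopifnot(inherits(reg, "cns_physiology"))
  out <- list(species = reg$species, parameters = unname(reg$parameters))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' The packaged default mouse CNS physiology
#'
#' Loads the curated mouse registry shipped with the package (volumes,
#' flows, barrier surfaces and effective-surface fractions, membrane
#' widths, compartmental pH values, phospholipid fraction and brain cell
#' count), applies the aggregation and derivation rules, and returns the
#' validated registry.
#'
#' @return a `cns_physiology` object.
#' @export
mouse_physiology <- function() {
  read_physiology(system.file("extdata", "mouse_physiology.json",
                              package = "cnspbpk", mustWork = TRUE))
}

#' Retrieve a canonical-unit parameter value
#'
#' @param reg `cns_physiology` object.
#' @param name parameter name, e.g. `"Q_CBF"`.
#' @return numeric value in canonical units (ml, ml/min, cm, cm2).
#' @export
phys_value <- function(reg, name) {
  v <- reg$values[[name]]
  if (is.null(v)) stop("unknown physiological parameter: ", name)
  v
}

#' Override physiology values (canonical units)
#'
#' Convenience for sensitivity analyses and tests: replaces final values
#' (given in the parameter's own reporting unit) and recanonicalizes.
#'
#' @param reg `cns_physiology` object.
#' @param ... named replacements in reporting units (ul, ml/min, cm2, um, pH).
#' @export
phys_override <- function(reg, ...) {
  repl <- list(...)
  for (nm in names(repl)) {
    if (is.null(reg$parameters[[nm]]))
      stop("unknown physiological parameter: ", nm)
    reg$parameters[[nm]]$final_value <- repl[[nm]]
    reg$parameters[[nm]]$aggregation <- "single"
  }
  reg$values <- .phys_canonical_values(reg$parameters)
  reg
}

#' Validate a physiology registry
#'
#' Report-only check.  Hard violations break model assumptions
#' (non-positive values, fluid volumes exceeding total brain volume,
#' fractions outside (0, 1], pH outside plausible range).  Soft warnings
#' surface internal inconsistencies carried over from the source
#' compilation (printed final values that disagree with the stated
#' aggregation of their literature values; CSF sub-volumes that do not
#' sum to the total CSF volume).
#'
#' @param reg `cns_physiology` object.
#' @return list with character vectors `violations` and `warnings`.
#' @export
validate_physiology <- function(reg) {
  p <- reg$parameters
  v <- reg$values
  bad <- character(0)
  soft <- character(0)
  for (nm in names(p)) {
    fv <- p[[nm]]$final_value
    if (!is.finite(fv) || fv <= 0)
      bad <- c(bad, sprintf("%s: final value must be positive (got %s)", nm, fv))
  }
  if (!is.null(v$V_ICF) && !is.null(v$V_ECF) && !is.null(v$V_brain_total) &&
      v$V_ICF + v$V_ECF >= v$V_brain_total)
    bad <- c(bad, "V_ICF + V_ECF must be smaller than V_brain_total")
  for (nm in grep("^f_(trans|para)_", names(p), value = TRUE)) {
    fv <- p[[nm]]$final_value
    if (!is.finite(fv) || fv <= 0 || fv > 1)
      bad <- c(bad, sprintf("%s: effective surface fraction outside (0, 1]", nm))
  }
  for (nm in grep("^pH_", names(p), value = TRUE)) {
    fv <- p[[nm]]$final_value
    if (fv < 3 || fv > 9)
      bad <- c(bad, sprintf("%s: pH outside [3, 9]", nm))
  }
  # aggregation consistency (soft: printed final may deviate from statistic)
  for (nm in names(p)) {
    z <- p[[nm]]
    if (identical(z$aggregation, "single") &&
        length(z$literature_values) > 1) {
      m <- mean(z$literature_values)
      if (abs(m - z$final_value) / z$final_value > 0.05)
        soft <- c(soft, sprintf(
          "%s: adopted final value %g differs from mean of literature values (%g)",
          nm, z$final_value, m))
    }
  }
  if (all(c("V_ventricles_total", "V_CM", "V_SAS", "V_CSF_total") %in% names(p))) {
    s <- p$V_ventricles_total$final_value + p$V_CM$final_value +
      p$V_SAS$final_value
    if (abs(s - p$V_CSF_total$final_value) / p$V_CSF_total$final_value > 0.02)
      soft <- c(soft, sprintf(
        "CSF sub-volumes sum to %g ul but total CSF volume is %g ul",
        s, p$V_CSF_total$final_value))
  }
  list(violations = bad, warnings = soft)
}

#' @export
print.cns_physiology <- function(x, ...) {
  cat("<cns_physiology>", x$species, "-", length(x$parameters), "parameters\n")
  df <- data.frame(
    parameter = names(x$parameters),
    final_value = vapply(x$parameters, `[[`, numeric(1), "final_value"),
    unit = vapply(x$parameters, `[[`, character(1), "unit"),
    aggregation = vapply(x$parameters, `[[`, character(1), "aggregation"),
    row.names = NULL
  )
  print(df, ...)
  invisible(x)
}
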