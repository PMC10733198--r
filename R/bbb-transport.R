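# Kp,uu,BBB estimation and asymmetry factors.
#
# Kp,uu,BBB is the steady-state ratio of unbound brain-ECF to unbound
# plasma concentration.  It is estimated either as the ratio of the
# brain-ECF to plasma AUC(0-inf) (linear systems), or as the ratio of
# influx to efflux clearance from a sequential fit of a one-compartment
# whole-brain model on top of a fixed plasma PK model.  Kp,uu values are
# converted into asymmetry factors that scale barrier influx/efflux
# clearances in the PBPK model to encode net active transport.

#' AUC to infinity by log-trapezoid plus terminal extrapolation
#'
#' Log-trapezoid on decreasing positive segments (arithmetic trapezoid
#' otherwise) up to the last observation, then `Clast/lambda_z`
#' extrapolation.  The terminal slope uses the last `n_tail` points with
#' an adjusted-R^2 safeguard.
#'
#' @param time,conc sampled curve (time in min, positive concentrations).
#' @param n_tail number of terminal points for the lambda_z regression.
#' @param min_adj_r2 minimum adjusted R^2 accepted for the terminal fit.
#' @return list with `auc`, `auc_last`, `lambda_z`, `extrap_frac`.
#' @export
auc_inf <- function(time, conc, n_tail = 3L, min_adj_r2 = 0.8) {
  stopifnot(length(time) == length(conc), length(time) >= 3,
            !is.unsorted(time))
  keep <- is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 3) stop("need at least 3 positive points")
  auc <- 0
  for (i in seq_len(length(time) - 1L)) {
    dt <- time[i + 1L] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    auc <- auc + if (c2 < c1 && c2 > 0) dt * (c1 - c2) / log(c1 / c2)
                 else dt * (c1 + c2) / 2
  }
  idx <- seq(length(time) - n_tail + 1L, length(time))
  lt <- time[idx]; lc <- log(conc[idx])
  if (any(diff(conc[idx]) >= 0))
    stop("terminal phase is not monotonically decreasing; ",
         "lambda_z is not estimable")
  fit <- stats::lm(lc ~ lt)
  lam <- -unname(stats::coef(fit)[2])
  ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
  if (n_tail > 2 && is.finite(ar2) && ar2 < min_adj_r2)
    stop(sprintf("terminal fit adjusted R^2 %.3f below %.2f", ar2, min_adj_r2))
  if (lam <= 0) stop("non-positive terminal slope; lambda_z not estimable")
  tail_auc <- conc[length(conc)] / lam
  list(auc = auc + tail_auc, auc_last = auc, lambda_z = lam,
       extrap_frac = tail_auc / (auc + tail_auc))
}

#' Kp,uu,BBB by the AUC-ratio method
#'
#' `AUC(0-inf)` of the unbound brain-ECF curve over that of the unbound
#' plasma curve.  For any linear plasma+brain system this equals the
#' influx/efflux clearance ratio.
#'
#' @param plasma_curve,ecf_curve data frames with `time_min` and
#'   `conc_ng_ml` (unbound concentrations).
#' @param ... passed to [auc_inf()].
#' @return list with `kpuu`, per-curve AUC detail.
#' @export
kpuu_from_auc <- function(plasma_curve, ecf_curve, ...) {
  ap <- auc_inf(plasma_curve$time_min, plasma_curve$conc_ng_ml, ...)
  ae <- auc_inf(ecf_curve$time_min, ecf_curve$conc_ng_ml, ...)
  list(kpuu = ae$auc / ap$auc, plasma = ap, ecf = ae)
}

#' Asymmetry factors from a Kp,uu value
#'
#' Net active transport is encoded by scaling one side of the barrier:
#' `Kpuu < 1` scales efflux (`AF_out = 1/Kpuu`), `Kpuu > 1` scales influx
#' (`AF_in = Kpuu`); the idle side stays at 1, so `AF_in / AF_out = Kpuu`
#' and at most one factor exceeds 1.  The side convention follows the
#' published usage of the model family and can be switched.
#'
#' @param kpuu positive Kp,uu value.
#' @param convention `"efflux_influx"` (default, as described) or
#'   `"influx_only"` (always scale influx: `AF_in = Kpuu`, `AF_out = 1`).
#' @return object of class `asymmetry_factors` with `AF_in`, `AF_out`.
#' @export
asymmetry_factors <- function(kpuu,
                              convention = c("efflux_influx", "influx_only")) {
  convention <- match.arg(convention)
  if (!is.finite(kpuu) || kpuu <= 0) stop("Kp,uu must be positive")
  af <- if (convention == "influx_only") {
    list(AF_in = kpuu, AF_out = 1)
  } else if (kpuu < 1) {
    list(AF_in = 1, AF_out = 1 / kpuu)
  } else {
    list(AF_in = kpuu, AF_out = 1)
  }
  class(af) <- "asymmetry_factors"
  af
}

#' @export
print.asymmetry_factors <- function(x, ...) {
  cat(sprintf("<asymmetry_factors> AF_in %.4g, AF_out %.4g (Kp,uu %.4g)\n",
              x$AF_in, x$AF_out, x$AF_in / x$AF_out))
  invisible(x)
}

#' Estimate BBB influx/efflux clearances from brain-ECF data
#'
#' Sequential fit: the plasma PK model is fixed and a one-compartment
#' whole-brain model `dA_br/dt = CL_in * Cu_p(t) - (CL_out/V) * A_br`
#' is fitted to unbound brain-ECF observations by pooled maximum
#' likelihood under proportional error.  `Kp,uu = CL_in / CL_out`.
#'
#' @param plasma_model fixed (typical-value) `plasma_pk_model`.
#' @param doses dose events shared with the plasma model.
#' @param ecf_observations data frame with `time_min`, `conc_ng_ml`
#'   (unbound ECF; a `matrix` column is filtered to `"brain_ecf"`).
#' @param V_brain_apparent apparent brain volume (ml); defaults to the
#'   mouse ECF volume 0.067 ml.
#' @param n_starts,seed multi-start control.
#' @return list with `CL_in`, `CL_out` (ml/min), `kpuu`, `ofv`,
#'   `convergence`, `boundary` flag.
#' @export
estimate_bbb_clearances <- function(plasma_model, doses, ecf_observations,
                                    V_brain_apparent = 0.067,
                                    n_starts = 3L, seed = 1L) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  if ("matrix" %in% names(ecf_observations))
    ecf_observations <- ecf_observations[ecf_observations$matrix == "brain_ecf", ]
  if ("bql" %in% names(ecf_observations))
    ecf_observations <- ecf_observations[!(ecf_observations$bql %in% 1), ]
  ecf_observations <- ecf_observations[
    is.finite(ecf_observations$conc_ng_ml) & ecf_observations$conc_ng_ml > 0, ]
  if (nrow(ecf_observations) == 0) stop("no usable brain-ECF observations")
  tobs <- ecf_observations$time_min
  obs <- ecf_observations$conc_ng_ml

  sysp <- .plasma_system(plasma_model)
  np <- nrow(sysp$A)
  inp <- .plasma_inputs(plasma_model, sysp, doses)
  fu <- plasma_model$fu_plasma
  ts <- sort(unique(tobs))

  predict_ecf <- function(cl_in, cl_out) {
    # plasma block + one brain state, coupled one-way via Cu,p = fu*Ac/Vc
    A <- rbind(cbind(sysp$A, 0), 0)
    A[np + 1, sysp$central] <- cl_in * fu / sysp$Vc
    A[np + 1, np + 1] <- -cl_out / V_brain_apparent
    inf2 <- lapply(inp$infusions, function(z) {
      z$rate <- c(z$rate, 0); z
    })
    bol2 <- lapply(inp$boluses, function(z) {
      z$amount <- c(z$amount, 0); z
    })
    sol <- solve_linear_system(A, numeric(np + 1), ts,
                               infusions = inf2, boluses = bol2)
    (sol$state[np + 1, ] / V_brain_apparent)[match(tobs, ts)]
  }
  obj <- function(lt) {
    pred <- pmax(predict_ecf(exp(lt[1]), exp(lt[2])), 1e-300)
    r <- obs - pred
    n <- length(obs)
    s2 <- max(mean(r^2 / pred^2), 1e-30)
    n * log(2 * pi * s2) + 2 * sum(log(pred)) + n
  }
  # heuristic start: CL_out from terminal washout scale, CL_in from peak
  st <- log(c(max(obs) * V_brain_apparent / max(1e-12, max(obs) * max(tobs) / 4),
              V_brain_apparent / max(tobs) * 10))
  st <- ifelse(is.finite(st), st, log(c(1e-3, 1e-2)))
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    jit <- if (k == 1) c(0, 0) else stats::runif(2, -1.5, 1.5)
    fit <- tryCatch(.optim_polish(st + jit, obj),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("brain clearance estimation failed to converge")
  cl_in <- exp(best$par[1]); cl_out <- exp(best$par[2])
  boundary <- cl_out < 1e-8
  if (boundary)
    warning("CL_out is at the lower boundary; Kp,uu is unreliable")
  list(CL_in = cl_in, CL_out = cl_out, kpuu = cl_in / cl_out,
       ofv = best$value, convergence = best$convergence,
       boundary = boundary)
}

#' Load the packaged Kp,uu,BBB table
#'
#' @return data frame with `name`, `kpuu_bbb`, `method`
#'   (`"literature"` or `"estimated"`).
#' @export
kpuu_table <- function() {
  raw <- jsonlite::read_json(system.file("extdata", "kpuu.json",
                                         package = "cnspbpk", mustWork = TRUE),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(rbind, lapply(raw$kpuu, function(z)
    data.frame(name = z$name, kpuu_bbb = z$kpuu_bbb, method = z$method)))
}
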