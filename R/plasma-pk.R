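# Compartmental plasma pharmacokinetic models.
#
# These serve three roles: forcing functions into the CNS PBPK model,
# population simulation with inter-individual variability (IIV) and
# residual error for visual predictive checks, and pooled
# maximum-likelihood estimation from plasma concentration data.
#
# Units: amounts ng, volumes ml, clearances ml/min, times min,
# concentrations ng/ml.

#' Construct a compartmental plasma PK model
#'
#' @param name drug / model label.
#' @param n_compartments 1, 2 or 3 disposition compartments.
#' @param CL central clearance (ml/min), > 0.
#' @param Vc central volume (ml), > 0.
#' @param Q2,Vp2 first peripheral inter-compartmental clearance (ml/min)
#'   and volume (ml); jointly zero or jointly positive.
#' @param Q3,Vp3 second peripheral pair.
#' @param ka first-order absorption rate (1/min); 0 means no depot.
#' @param zero_order_duration zero-order release duration (min): the dose
#'   is released at constant rate over this window (into the depot for
#'   extravascular routes, into the central compartment for IV).
#' @param route one of `"IV"`, `"IP"`, `"PO"`, `"SC"`.  Extravascular
#'   routes with `ka > 0` use a depot compartment; with `ka = 0` (and no
#'   zero-order window) absorption is treated as instantaneous and the
#'   dose enters the central compartment directly.
#' @param fu_plasma plasma unbound fraction.
#' @param iiv named list of exponential-model IIV variances (omega^2) for
#'   `CL`, `Q2`, `Q3`, `Vc`, `Vp2`, `Vp3`, `ka`; missing entries are 0.
#' @param residual list with `prop` (proportional error variance) and
#'   `add` (additive error variance, (ng/ml)^2).
#' @param dose_mg_kg nominal study dose, for the fixture record.
#' @return object of class `plasma_pk_model`.
#' @export
plasma_pk_model <- function(name = "model", n_compartments = 1,
                            CL, Vc, Q2 = 0, Vp2 = 0, Q3 = 0, Vp3 = 0,
                            ka = 0, zero_order_duration = 0,
                            route = c("IV", "IP", "PO", "SC"),
                            fu_plasma = 1,
                            iiv = list(), residual = list(prop = 0, add = 0),
                            dose_mg_kg = NA_real_) {
  route <- match.arg(route)
  stopifnot(CL > 0, Vc > 0, n_compartments %in% 1:3,
            zero_order_duration >= 0, ka >= 0)
  if ((Q2 > 0) != (Vp2 > 0) || (Q3 > 0) != (Vp3 > 0))
    stop("peripheral Q and Vp must be jointly zero or jointly positive")
  iiv_full <- list(CL = 0, Q2 = 0, Q3 = 0, Vc = 0, Vp2 = 0, Vp3 = 0, ka = 0)
  iiv_full[names(iiv)] <- iiv
  if (any(unlist(iiv_full) < 0)) stop("IIV variances must be >= 0")
  residual_full <- list(prop = 0, add = 0)
  residual_full[names(residual)] <- residual
  if (any(unlist(residual_full) < 0)) stop("residual variances must be >= 0")
  structure(list(name = name, n_compartments = n_compartments,
                 CL = CL, Vc = Vc, Q2 = Q2, Vp2 = Vp2, Q3 = Q3, Vp3 = Vp3,
                 ka = ka, zero_order_duration = zero_order_duration,
                 route = route, fu_plasma = fu_plasma,
                 iiv = iiv_full, residual = residual_full,
                 dose_mg_kg = dose_mg_kg),
            class = "plasma_pk_model")
}

#' @export
print.plasma_pk_model <- function(x, ...) {
  cat(sprintf("<plasma_pk_model> %s: %d-compartment, route %s\n",
              x$name, x$n_compartments, x$route))
  cat(sprintf("  CL %.4g ml/min, Vc %.4g ml", x$CL, x$Vc))
  if (x$Q2 > 0) cat(sprintf(", Q2 %.4g, Vp2 %.4g", x$Q2, x$Vp2))
  if (x$Q3 > 0) cat(sprintf(", Q3 %.4g, Vp3 %.4g", x$Q3, x$Vp3))
  if (x$ka > 0) cat(sprintf(", ka %.4g 1/min", x$ka))
  if (x$zero_order_duration > 0)
    cat(sprintf(", D0 %.4g min", x$zero_order_duration))
  cat("\n")
  invisible(x)
}

#' Dose events
#'
#' @param amount_ng dose amount in ng (use [dose_from_mg_kg()] to convert
#'   a body-weight dose).
#' @param time_min dosing time (min).
#' @return object of class `dose_event`.
#' @export
dose_event <- function(amount_ng, time_min = 0) {
  stopifnot(amount_ng > 0, time_min >= 0)
  structure(list(amount = amount_ng, time = time_min), class = "dose_event")
}

#' Convert a mg/kg dose to ng
#'
#' Body weights are not part of the packaged parameter sets; the default
#' 0.025 kg is a conventional adult-mouse weight and is configurable.
#'
#' @param dose_mg_kg dose in mg per kg body weight.
#' @param body_weight_kg body weight in kg.
#' @export
dose_from_mg_kg <- function(dose_mg_kg, body_weight_kg = 0.025) {
  stopifnot(dose_mg_kg > 0, body_weight_kg > 0)
  dose_mg_kg * body_weight_kg * 1e6   # mg -> ng
}

# does this model route the dose through a depot compartment?
.has_depot <- function(model) {
  model$route != "IV" && model$ka > 0
}

# Build the linear-system pieces for one parameter realization.
# States: [depot?], central, [periph2], [periph3].
.plasma_system <- function(model, pars = NULL) {
  p <- if (is.null(pars)) model else utils::modifyList(model, pars)
  depot <- .has_depot(model)
  labs <- c(if (depot) "depot", "central",
            if (p$Q2 > 0) "periph2", if (p$Q3 > 0) "periph3")
  n <- length(labs)
  A <- matrix(0, n, n, dimnames = list(labs, labs))
  ic <- which(labs == "central")
  A[ic, ic] <- -p$CL / p$Vc
  if (depot) {
    id <- which(labs == "depot")
    A[id, id] <- -p$ka
    A[ic, id] <- p$ka
  }
  if (p$Q2 > 0) {
    i2 <- which(labs == "periph2")
    A[ic, ic] <- A[ic, ic] - p$Q2 / p$Vc
    A[i2, ic] <- p$Q2 / p$Vc
    A[ic, i2] <- p$Q2 / p$Vp2
    A[i2, i2] <- -p$Q2 / p$Vp2
  }
  if (p$Q3 > 0) {
    i3 <- which(labs == "periph3")
    A[ic, ic] <- A[ic, ic] - p$Q3 / p$Vc
    A[i3, ic] <- p$Q3 / p$Vc
    A[ic, i3] <- p$Q3 / p$Vp3
    A[i3, i3] <- -p$Q3 / p$Vp3
  }
  list(A = A, labels = labs, central = ic,
       target = if (depot) which(labs == "depot") else ic,
       Vc = p$Vc)
}

# Translate dose events into boluses / zero-order infusions on the system
.plasma_inputs <- function(model, sys, doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  infusions <- list()
  boluses <- list()
  n <- nrow(sys$A)
  for (d in doses) {
    vec <- numeric(n)
    if (model$zero_order_duration > 0) {
      vec[sys$target] <- d$amount / model$zero_order_duration
      infusions[[length(infusions) + 1L]] <-
        list(start = d$time, end = d$time + model$zero_order_duration,
             rate = vec)
    } else {
      vec[sys$target] <- d$amount
      boluses[[length(boluses) + 1L]] <- list(time = d$time, amount = vec)
    }
  }
  list(infusions = infusions, boluses = boluses)
}

# draw one subject's parameter set under the exponential IIV model
.draw_subject_pars <- function(model) {
  pars <- list()
  for (nm in names(model$iiv)) {
    w2 <- model$iiv[[nm]]
    if (w2 > 0 && !is.null(model[[nm]]) && model[[nm]] > 0)
      pars[[nm]] <- model[[nm]] * exp(stats::rnorm(1L, 0, sqrt(w2)))
  }
  pars
}

#' Simulate plasma concentration-time profiles
#'
#' Each subject draws `eta ~ N(0, omega^2)` per parameter with IIV and
#' uses `theta * exp(eta)`.  The kinetic system is solved exactly; with
#' all variances zero and one subject the output is deterministic.
#'
#' @param model a `plasma_pk_model`.
#' @param doses a `dose_event` or list of them.
#' @param times sorted non-negative sampling times (min).
#' @param n_subjects number of subjects.
#' @param seed optional RNG seed for reproducibility.
#' @return data.frame with `id`, `time_min`, `conc_ng_ml` (total) and
#'   `conc_u_ng_ml` (unbound = `fu_plasma` x total).
#' @export
simulate_plasma <- function(model, doses, times, n_subjects = 1L,
                            seed = NULL) {
  stopifnot(inherits(model, "plasma_pk_model"),
            !is.unsorted(times), all(times >= 0), n_subjects >= 1L)
  if (model$route != "IV" && model$ka <= 0 && model$zero_order_duration <= 0)
    message("note: extravascular route with ka = 0 and no zero-order window; ",
            "dose treated as an instantaneous bolus into the central compartment")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pars <- .draw_subject_pars(model)
    sys <- .plasma_system(model, pars)
    inp <- .plasma_inputs(model, sys, doses)
    sol <- solve_linear_system(sys$A, numeric(nrow(sys$A)), times,
                               infusions = inp$infusions,
                               boluses = inp$boluses)
    conc <- sol$state[sys$central, ] / sys$Vc
    out[[i]] <- data.frame(id = i, time_min = times,
                           conc_ng_ml = conc,
                           conc_u_ng_ml = model$fu_plasma * conc)
  }
  do.call(rbind, out)
}

#' Add residual error to model predictions
#'
#' Combined proportional + additive model:
#' `obs = pred * (1 + eps_p) + eps_a` with
#' `eps_p ~ N(0, prop)` and `eps_a ~ N(0, add)`.
#'
#' @param pred numeric vector of predictions, or a data frame with a
#'   `conc_ng_ml` column (a matching noisy column is appended).
#' @param residual list with variances `prop` and `add`.
#' @param seed optional RNG seed.
#' @return same shape as `pred` with noise applied.
#' @export
add_residual_error <- function(pred, residual = list(prop = 0, add = 0),
                               seed = NULL) {
  prop <- residual$prop %||% 0
  addv <- residual$add %||% 0
  stopifnot(prop >= 0, addv >= 0)
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(x) {
    x * (1 + stats::rnorm(length(x), 0, sqrt(prop))) +
      stats::rnorm(length(x), 0, sqrt(addv))
  }
  if (is.data.frame(pred)) {
    pred$conc_ng_ml <- noisy(pred$conc_ng_ml)
    if ("conc_u_ng_ml" %in% names(pred)) pred$conc_u_ng_ml <- NULL
    pred
  } else noisy(pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unbound-plasma forcing function
#'
#' Returns a continuous function `t -> Cu,plasma(t)` (ng/ml) for the
#' population-typical model, evaluated exactly by the closed-form
#' propagator (identical to [simulate_plasma()] with all variances zero).
#' The returned function carries the model and doses as attributes so
#' the CNS simulator can couple to the plasma system exactly.
#'
#' @param model a `plasma_pk_model`.
#' @param doses a `dose_event` or list of them.
#' @return vectorized function of time (min); 0 before the first dose.
#' @export
plasma_forcing <- function(model, doses) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  sys <- .plasma_system(model)
  inp <- .plasma_inputs(model, sys, doses)
  fu <- model$fu_plasma
  f <- function(t) {
    t <- as.numeric(t)
    out <- numeric(length(t))
    ord <- order(t)
    ts <- sort(unique(pmax(t, 0)))
    sol <- solve_linear_system(sys$A, numeric(nrow(sys$A)), ts,
                               infusions = inp$infusions,
                               boluses = inp$boluses)
    cu <- fu * sol$state[sys$central, ] / sys$Vc
    out <- cu[match(pmax(t, 0), ts)]
    out[t < min(vapply(doses, `[[`, numeric(1), "time"))] <- 0
    out
  }
  attr(f, "model") <- model
  attr(f, "doses") <- doses
  class(f) <- c("plasma_forcing", "function")
  f
}

#' Load the packaged plasma PK parameter sets
#'
#' Ten per-drug compartmental parameter sets (structural parameters, IIV
#' variances, residual-error variances, nominal dose and route)
#' transcribed into `inst/extdata/plasma_models.json`.
#'
#' @param names optional subset of drug names.
#' @return named list of `plasma_pk_model` objects.
#' @export
plasma_models <- function(names = NULL) {
  raw <- jsonlite::read_json(system.file("extdata", "plasma_models.json",
                                         package = "cnspbpk", mustWork = TRUE),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  mods <- lapply(raw$models, function(z) {
    plasma_pk_model(name = z$name, n_compartments = z$n_compartments,
                    CL = z$CL, Vc = z$Vc, Q2 = z$Q2, Vp2 = z$Vp2,
                    ka = z$ka, zero_order_duration = z$zero_order_duration,
                    route = z$route, fu_plasma = z$fu_plasma,
                    iiv = z$iiv, residual = z$residual,
                    dose_mg_kg = z$dose_mg_kg)
  })
  names(mods) <- vapply(mods, `[[`, character(1), "name")
  if (!is.null(names)) {
    miss <- setdiff(names, base::names(mods))
    if (length(miss)) stop("unknown model(s): ", paste(miss, collapse = ", "))
    mods <- mods[names]
  }
  mods
}
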