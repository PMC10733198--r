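# Synthetic microdialysis studies with known ground truth.
#
# The raw in vivo datasets behind the packaged parameter sets are not
# publicly available, so every pipeline stage is exercised on synthetic
# studies that emulate their statistical structure: sparse destructive
# plasma sampling (a few animals per time point), serial interval-
# averaged brain-ECF microdialysis collections, lognormal
# inter-individual variability and proportional(+additive) residual
# error.  Synthetic data are labelled as such throughout.

#' Describe a synthetic study design
#'
#' Defaults mimic a sparse destructive plasma design (3 animals per
#' sampling time) plus serial 20-minute dialysate collections, which is
#' representative of the underlying study types; real per-study
#' schedules are not reproduced.
#'
#' @param plasma_times plasma sampling times (min).
#' @param animals_per_time animals sacrificed per plasma time
#'   (destructive sampling); set `serial_plasma = TRUE` for serial
#'   sampling instead.
#' @param serial_plasma logical; if TRUE, `n_plasma_animals` animals are
#'   each sampled at all `plasma_times`.
#' @param n_plasma_animals number of serial plasma animals.
#' @param md_windows 2-column matrix of microdialysis collection
#'   start/end times (min), non-overlapping.
#' @param n_md_animals number of microdialysis animals.
#' @param dose_mg_kg,route,body_weight_kg dosing regimen.
#' @param md_recovery probe relative recovery applied multiplicatively
#'   to ECF concentrations (default 1: reported concentrations are
#'   recovery-corrected).
#' @return object of class `study_design`.
#' @export
study_design <- function(plasma_times = c(5, 15, 30, 60, 120, 240, 360),
                         animals_per_time = 3L, serial_plasma = FALSE,
                         n_plasma_animals = 8L,
                         md_windows = cbind(seq(0, 340, by = 20),
                                            seq(20, 360, by = 20)),
                         n_md_animals = 4L,
                         dose_mg_kg = 10, route = "IV",
                         body_weight_kg = 0.025,
                         md_recovery = 1) {
  md_windows <- as.matrix(md_windows)
  stopifnot(ncol(md_windows) == 2, all(md_windows[, 2] > md_windows[, 1]),
            n_md_animals >= 0, animals_per_time >= 1,
            md_recovery > 0, md_recovery <= 1)
  if (nrow(md_windows) > 1) {
    o <- order(md_windows[, 1])
    if (any(md_windows[o, 1][-1] < md_windows[o, 2][-nrow(md_windows)]))
      stop("microdialysis windows must be non-overlapping")
  }
  res <- list(plasma_times = sort(plasma_times),
              animals_per_time = animals_per_time,
              serial_plasma = serial_plasma,
              n_plasma_animals = n_plasma_animals,
              md_windows = md_windows, n_md_animals = n_md_animals,
              dose_mg_kg = dose_mg_kg, route = route,
              body_weight_kg = body_weight_kg, md_recovery = md_recovery)
  class(res) <- "study_design"
  res
}

#' Bundle a generating truth
#'
#' @param plasma_model generating `plasma_pk_model` (its `iiv` and
#'   `residual` slots are the generative noise model).
#' @param physiology `cns_physiology` registry.
#' @param drug `drug_record` (with `p_trans`).
#' @param kpuu true Kp,uu,BBB (defaults to the drug record's value).
#' @param md_residual residual-error variances for the microdialysis
#'   observations (default proportional 0.01).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(plasma_model, physiology, drug,
                         kpuu = drug$kpuu_bbb,
                         md_residual = list(prop = 0.01, add = 0)) {
  stopifnot(inherits(plasma_model, "plasma_pk_model"),
            inherits(drug, "drug_record"), kpuu > 0)
  res <- list(plasma_model = plasma_model, physiology = physiology,
              drug = drug, kpuu = kpuu, md_residual = md_residual)
  class(res) <- "ground_truth"
  res
}

#' Time-average of a concentration curve over a collection window
#'
#' Microdialysis reports the average unbound concentration over each
#' collection interval; computed here by adaptive quadrature.
#'
#' @param curve function `t -> conc` (e.g. a [plasma_forcing()] result
#'   or an interpolation of a simulated profile).
#' @param window length-2 numeric `c(start, end)` in min.
#' @param n_sub number of Simpson sub-intervals (even; the composite rule
#'   is exact for linear curves and well below 1e-6 relative for smooth
#'   kinetic profiles at the default resolution).
#' @return average concentration (ng/ml).
#' @export
interval_average <- function(curve, window, n_sub = 400L) {
  stopifnot(is.function(curve), length(window) == 2, window[2] > window[1],
            n_sub %% 2 == 0)
  h <- (window[2] - window[1]) / n_sub
  tt <- window[1] + h * (0:n_sub)
  y <- vapply(tt, function(t) curve(t), numeric(1))
  if (any(!is.finite(y)))
    stop("curve not finite inside the collection window")
  w <- c(1, rep(c(4, 2), length.out = n_sub - 1), 1)
  sum(w * y) * h / 3 / (window[2] - window[1])
}

#' Generate a complete synthetic mouse PK study
#'
#' Per-animal parameters are drawn with exponential IIV from the truth's
#' plasma model; plasma observations follow the design's destructive or
#' serial schedule with the model's residual error; brain-ECF
#' observations are interval averages of each animal's simulated CNS ECF
#' profile over the microdialysis windows, scaled by probe recovery,
#' with the truth's microdialysis residual error.  Fully reproducible
#' from the seed.
#'
#' @param truth `ground_truth`.
#' @param design `study_design`.
#' @param seed RNG seed.
#' @return list with `observations` (long format: `id`, `time_min`,
#'   `matrix`, `conc_ng_ml`, `bql`), `doses` (`id`, `time_min`,
#'   `dose_mg_kg`, `route`), `dose_ng`, `truth`, `design`.
#' @export
generate_study <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"))
  set.seed(seed)
  pm <- truth$plasma_model
  dose_ng <- dose_from_mg_kg(design$dose_mg_kg, design$body_weight_kg)
  doses <- list(dose_event(dose_ng, 0))
  model_cns <- cns_model(truth$physiology, truth$drug,
                         af = asymmetry_factors(truth$kpuu))
  t_end <- max(design$plasma_times, design$md_windows)

  draw_animal_model <- function() {
    pars <- .draw_subject_pars(pm)
    if (length(pars)) utils::modifyList(pm, pars) else pm
  }

  obs <- list()
  nid <- 0L
  # ---- plasma arm -------------------------------------------------------
  if (design$serial_plasma) {
    schedule <- replicate(design$n_plasma_animals, design$plasma_times,
                          simplify = FALSE)
  } else {
    schedule <- unlist(lapply(design$plasma_times, function(tt)
      replicate(design$animals_per_time, tt, simplify = FALSE)),
      recursive = FALSE)
  }
  for (tt in schedule) {
    nid <- nid + 1L
    mi <- draw_animal_model()
    sys <- .plasma_system(mi)
    inp <- .plasma_inputs(mi, sys, doses)
    sol <- solve_linear_system(sys$A, numeric(nrow(sys$A)), tt,
                               infusions = inp$infusions,
                               boluses = inp$boluses)
    pred <- sol$state[sys$central, ] / sys$Vc
    noisy <- add_residual_error(pred, pm$residual)
    obs[[length(obs) + 1L]] <- data.frame(
      id = nid, time_min = tt, matrix = "plasma",
      conc_ng_ml = noisy, bql = as.integer(noisy <= 0))
  }
  # ---- microdialysis arm ------------------------------------------------
  if (design$n_md_animals > 0) {
    grid <- sort(unique(c(seq(0, t_end, length.out = 241L),
                          as.vector(design$md_windows))))
    for (j in seq_len(design$n_md_animals)) {
      nid <- nid + 1L
      mi <- draw_animal_model()
      sim <- simulate_cns(model_cns, plasma_forcing(mi, doses),
                          t_end = t_end, times = grid)
      ecf_fun <- stats::approxfun(sim$times, sim$conc["ECF", ], rule = 2)
      avg <- apply(design$md_windows, 1, function(w)
        interval_average(ecf_fun, w))
      avg <- avg * design$md_recovery
      noisy <- add_residual_error(avg, truth$md_residual)
      mid <- rowMeans(design$md_windows)
      obs[[length(obs) + 1L]] <- data.frame(
        id = nid, time_min = mid, matrix = "brain_ecf",
        conc_ng_ml = noisy, bql = as.integer(noisy <= 0))
    }
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  dosing <- data.frame(id = seq_len(nid), time_min = 0,
                       dose_mg_kg = design$dose_mg_kg, route = design$route)
  list(observations = observations, doses = dosing, dose_ng = dose_ng,
       truth = truth, design = design)
}
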