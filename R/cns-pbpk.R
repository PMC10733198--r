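# The CNS PBPK system.
#
# Eight physiological compartments -- brain microvasculature (MV), brain
# extracellular fluid (ECF), brain intracellular fluid (ICF), lysosomes
# (LYS), and the CSF cascade lateral ventricles (LV) -> third+fourth
# ventricles (TFV) -> cisterna magna (CM) -> subarachnoid space (SAS) --
# exchanging by passive transcellular permeation (neutral species only),
# paracellular diffusion (all unbound species), bulk flows, and
# asymmetry-factor-scaled active transport at the BBB and BCSFB.  The
# unbound plasma concentration enters as a forcing function through the
# cerebral blood flow; no mass is returned to the plasma model (its
# disposition already accounts for all elimination).
#
# States are amounts (ng); all fluxes are linear, so simulation and
# steady states are computed exactly (see linear-ode.R).

.CNS_STATES <- c("MV", "ECF", "ICF", "LYS", "LV", "TFV", "CM", "SAS")

#' Assemble the drug-specific clearance table
#'
#' Combines physiology (surfaces, effective-surface fractions, widths),
#' drug properties (passive transcellular permeability `P_trans`,
#' molecular-weight-derived paracellular permeability, neutral fractions,
#' cellular unbound fraction) and asymmetry factors into the clearance
#' terms of the ODE system.  Transcellular terms act on the neutral
#' unbound species of each donor compartment; paracellular terms act on
#' total unbound drug and are symmetric before asymmetry scaling.
#'
#' @param physiology `cns_physiology` registry.
#' @param drug `drug_record` with `p_trans` set (cm/min).
#' @param af BBB `asymmetry_factors`.
#' @param af_bcsfb BCSFB `asymmetry_factors` (default no asymmetry).
#' @return named list of clearances (ml/min), neutral fractions and
#'   binding fractions.
#' @export
assemble_clearances <- function(physiology, drug,
                                af = asymmetry_factors(1),
                                af_bcsfb = asymmetry_factors(1)) {
  if (is.null(drug$p_trans))
    stop("drug '", drug$name, "' has no passive transcellular permeability ",
         "(p_trans); supply one (see estimate_transcellular_permeability)")
  pv <- function(nm) phys_value(physiology, nm)
  w_bbb_um <- physiology$parameters$w_BBB$final_value
  w_bcsfb_um <- physiology$parameters$w_BCSFB$final_value
  p_para_bbb <- paracellular_permeability(drug, w_bbb_um)
  p_para_bcsfb <- paracellular_permeability(drug, w_bcsfb_um)
  fn <- list(plasma = fraction_neutral(pv("pH_plasma"), drug),
             ecf    = fraction_neutral(pv("pH_ECF"), drug),
             icf    = fraction_neutral(pv("pH_ICF"), drug),
             lys    = fraction_neutral(pv("pH_LYS"), drug),
             csf    = fraction_neutral(pv("pH_CSF"), drug))
  list(
    CL_BBB_trans   = drug$p_trans * pv("SA_BBB") * pv("f_trans_BBB"),
    CL_BBB_para    = p_para_bbb * pv("SA_BBB") * pv("f_para_BBB"),
    CL_BCSFB_trans = drug$p_trans * pv("SA_BCSFB") * pv("f_trans_BCSFB"),
    CL_BCSFB_para  = p_para_bcsfb * pv("SA_BCSFB") * pv("f_para_BCSFB"),
    CL_BCM         = drug$p_trans * pv("SA_BCM"),
    CL_LYS         = drug$p_trans * pv("SA_LYS"),
    fn = fn,
    fu_cell = unbound_fraction_cells(drug, pv("f_phospholipid")),
    AF_in = af$AF_in, AF_out = af$AF_out,
    AFb_in = af_bcsfb$AF_in, AFb_out = af_bcsfb$AF_out
  )
}

#' Assemble a CNS PBPK model
#'
#' @param physiology `cns_physiology` registry (see [mouse_physiology()]).
#' @param drug `drug_record`; must carry `p_trans`.
#' @param af BBB asymmetry factors; defaults to
#'   `asymmetry_factors(drug$kpuu_bbb)` when the drug record carries a
#'   Kp,uu value, otherwise no asymmetry.
#' @param af_bcsfb BCSFB asymmetry factors (default none: no CSF data
#'   constrain them).
#' @param bcsfb_split fractions of the BCSFB flux routed to the lateral
#'   and third+fourth ventricles (must sum to 1).
#' @return object of class `cns_model` holding the physiology, drug,
#'   clearance table, system matrix and forcing coefficient.
#' @export
cns_model <- function(physiology, drug, af = NULL,
                      af_bcsfb = asymmetry_factors(1),
                      bcsfb_split = c(0.5, 0.5)) {
  stopifnot(inherits(physiology, "cns_physiology"),
            inherits(drug, "drug_record"),
            length(bcsfb_split) == 2, abs(sum(bcsfb_split) - 1) < 1e-12)
  if (is.null(af)) {
    af <- if (!is.null(drug$kpuu_bbb)) asymmetry_factors(drug$kpuu_bbb)
          else asymmetry_factors(1)
  }
  val <- validate_physiology(physiology)
  if (length(val$violations))
    stop("invalid physiology: ", paste(val$violations, collapse = "; "))
  cl <- assemble_clearances(physiology, drug, af, af_bcsfb)
  pv <- function(nm) phys_value(physiology, nm)
  V <- c(MV = pv("V_MV"), ECF = pv("V_ECF"), ICF = pv("V_ICF"),
         LYS = pv("V_LYS_total"), LV = pv("V_LV"), TFV = pv("V_TFV"),
         CM = pv("V_CM"), SAS = pv("V_SAS"))
  Q_CBF <- pv("Q_CBF"); Q_ECF <- pv("Q_ECF"); Q_CSF <- pv("Q_CSF")

  # per-direction barrier clearances (ml/min)
  bbb_in  <- cl$AF_in  * (cl$CL_BBB_trans * cl$fn$plasma + cl$CL_BBB_para)
  bbb_out <- cl$AF_out * (cl$CL_BBB_trans * cl$fn$ecf    + cl$CL_BBB_para)
  bcsfb_in  <- cl$AFb_in  * (cl$CL_BCSFB_trans * cl$fn$plasma + cl$CL_BCSFB_para)
  bcsfb_out <- cl$AFb_out * (cl$CL_BCSFB_trans * cl$fn$csf    + cl$CL_BCSFB_para)
  bcm_in  <- cl$CL_BCM * cl$fn$ecf                 # ECF -> ICF
  bcm_out <- cl$CL_BCM * cl$fn$icf * cl$fu_cell    # ICF -> ECF (unbound)
  lys_in  <- cl$CL_LYS * cl$fn$icf * cl$fu_cell    # ICF -> LYS
  lys_out <- cl$CL_LYS * cl$fn$lys                 # LYS -> ICF

  s <- .CNS_STATES
  A <- matrix(0, 8, 8, dimnames = list(s, s))
  add <- function(to, from, cl_ml_min) {
    # flux = cl * C_from = cl/V_from * A_from
    k <- cl_ml_min / V[[from]]
    A[to, from] <<- A[to, from] + k
    A[from, from] <<- A[from, from] - k
  }
  # MV: perfusion outflow (venous sink) and barrier exchange
  A["MV", "MV"] <- A["MV", "MV"] - Q_CBF / V[["MV"]]
  add("ECF", "MV", bbb_in);  add("MV", "ECF", bbb_out)
  add("LV",  "MV", bcsfb_split[1] * bcsfb_in)
  add("MV",  "LV", bcsfb_split[1] * bcsfb_out)
  add("TFV", "MV", bcsfb_split[2] * bcsfb_in)
  add("MV",  "TFV", bcsfb_split[2] * bcsfb_out)
  # brain cell membrane and lysosomal exchange
  add("ICF", "ECF", bcm_in); add("ECF", "ICF", bcm_out)
  add("LYS", "ICF", lys_in); add("ICF", "LYS", lys_out)
  # bulk flows: ECF flow to cisterna magna; CSF cascade; SAS outflow sink
  add("CM", "ECF", Q_ECF)
  add("TFV", "LV", Q_CSF)
  add("CM", "TFV", Q_CSF)
  add("SAS", "CM", Q_CSF + Q_ECF)
  A["SAS", "SAS"] <- A["SAS", "SAS"] - (Q_CSF + Q_ECF) / V[["SAS"]]

  b_unit <- c(MV = Q_CBF, ECF = 0, ICF = 0, LYS = 0,
              LV = 0, TFV = 0, CM = 0, SAS = 0)   # per unit Cu,plasma
  sink_row <- c(MV = Q_CBF / V[["MV"]], ECF = 0, ICF = 0, LYS = 0,
                LV = 0, TFV = 0, CM = 0,
                SAS = (Q_CSF + Q_ECF) / V[["SAS"]])
  res <- list(physiology = physiology, drug = drug, af = af,
              af_bcsfb = af_bcsfb, clearances = cl, volumes = V,
              flows = c(Q_CBF = Q_CBF, Q_ECF = Q_ECF, Q_CSF = Q_CSF),
              A = A, b_unit = b_unit, sink_row = sink_row)
  class(res) <- "cns_model"
  res
}

#' @export
print.cns_model <- function(x, ...) {
  cat(sprintf("<cns_model> %s in %s physiology\n", x$drug$name,
              x$physiology$species))
  cat(sprintf("  AF_in %.4g, AF_out %.4g; fu,cell %.4g\n",
              x$af$AF_in, x$af$AF_out, x$clearances$fu_cell))
  invisible(x)
}

#' Unbound-concentration conversion factors per compartment
#'
#' ECF and CSF compartments are protein-poor (unbound = total/volume);
#' ICF applies the cellular unbound fraction; MV is unbound plasma water;
#' LYS is reported as total intralysosomal concentration.
#' @keywords internal
.cns_conc_factors <- function(model) {
  f <- 1 / model$volumes
  f[["ICF"]] <- f[["ICF"]] * model$clearances$fu_cell
  f
}

#' The ODE right-hand side of an assembled CNS model
#'
#' Exposed for audit: `f(t, state)` returns `d(state)/dt` given the
#' forcing function.  Simulation itself uses the exact linear solver.
#'
#' @param model `cns_model`.
#' @param forcing function `t -> Cu,plasma(t)` (ng/ml).
#' @return function `(t, state) -> derivative vector`.
#' @export
cns_rate_function <- function(model, forcing = function(t) 0) {
  function(t, state) {
    drop(model$A %*% state) + model$b_unit * forcing(t)
  }
}

#' Simulate the CNS PBPK model
#'
#' The forcing is either a [plasma_forcing()] function (the plasma
#' system is then coupled exactly as an upper block of one linear
#' system) or a constant unbound plasma concentration.  Returns unbound
#' concentration-time profiles for all compartments plus a mass-balance
#' audit (CNS content + cumulative outflow - cumulative inflow, relative
#' to total input).
#'
#' @param model `cns_model`.
#' @param forcing `plasma_forcing` function or a single non-negative
#'   number (constant Cu,plasma, ng/ml).
#' @param t_end simulation horizon (min).
#' @param n_grid number of evenly spaced output points on `[0, t_end]`.
#' @param times optional explicit output times (overrides `n_grid`).
#' @return object of class `cns_sim`: `times`, `conc` (compartments x
#'   times, ng/ml unbound; `LYS` is total), `amounts`,
#'   `mass_balance_rel`, `forcing_conc`.
#' @export
simulate_cns <- function(model, forcing, t_end, n_grid = 241L,
                         times = NULL) {
  stopifnot(inherits(model, "cns_model"), t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = n_grid)
  stopifnot(!is.unsorted(times), all(times >= 0))
  nc <- 8L
  if (inherits(forcing, "plasma_forcing")) {
    pm <- attr(forcing, "model"); doses <- attr(forcing, "doses")
    sysp <- .plasma_system(pm)
    np <- nrow(sysp$A)
    inp <- .plasma_inputs(pm, sysp, doses)
    A <- matrix(0, np + nc, np + nc)
    A[seq_len(np), seq_len(np)] <- sysp$A
    A[np + seq_len(nc), np + seq_len(nc)] <- model$A
    A[np + seq_len(nc), sysp$central] <-
      model$b_unit * pm$fu_plasma / sysp$Vc
    ext <- function(v) c(v, numeric(nc))
    infusions <- lapply(inp$infusions, function(z) { z$rate <- ext(z$rate); z })
    boluses <- lapply(inp$boluses, function(z) { z$amount <- ext(z$amount); z })
    sol <- solve_linear_system(A, numeric(np + nc), times,
                               infusions = infusions, boluses = boluses,
                               cumulative = TRUE)
    amounts <- sol$state[np + seq_len(nc), , drop = FALSE]
    forcing_conc <- pm$fu_plasma * sol$state[sysp$central, ] / sysp$Vc
    # mass balance on the CNS block
    cum_in <- model$flows[["Q_CBF"]] * pm$fu_plasma / sysp$Vc *
      sol$integral[sysp$central, ]
    cum_out <- drop(model$sink_row %*% sol$integral[np + seq_len(nc), ,
                                                    drop = FALSE])
  } else if (is.numeric(forcing) && length(forcing) == 1L) {
    stopifnot(forcing >= 0)
    b <- model$b_unit * forcing
    sol <- solve_linear_system(model$A, numeric(nc), times,
                               infusions = list(list(start = 0,
                                                     end = max(times) + 1,
                                                     rate = b)),
                               cumulative = TRUE)
    amounts <- sol$state
    forcing_conc <- rep(forcing, length(times))
    cum_in <- model$flows[["Q_CBF"]] * forcing * times
    cum_out <- drop(model$sink_row %*% sol$integral)
  } else {
    stop("forcing must be a plasma_forcing function or a single number")
  }
  rownames(amounts) <- .CNS_STATES
  cf <- .cns_conc_factors(model)
  conc <- amounts * as.numeric(cf[.CNS_STATES])
  content <- colSums(amounts)
  denom <- pmax(cum_in, max(cum_in) * 1e-6, .Machine$double.xmin)
  mb <- (content + cum_out - cum_in) / denom
  res <- list(times = times, conc = conc, amounts = amounts,
              mass_balance_rel = mb, forcing_conc = forcing_conc,
              model = model)
  class(res) <- "cns_sim"
  res
}

#' @export
print.cns_sim <- function(x, ...) {
  cat(sprintf("<cns_sim> %s: %d time points over [%.4g, %.4g] min\n",
              x$model$drug$name, length(x$times), min(x$times), max(x$times)))
  cmax <- apply(x$conc, 1, max)
  print(signif(cmax, 4))
  invisible(x)
}

#' Tidy data frame of a CNS simulation
#'
#' @param x `cns_sim` object.
#' @param ... unused.
#' @return data frame `time_min`, `compartment`, `conc_ng_ml`.
#' @export
as.data.frame.cns_sim <- function(x, ...) {
  data.frame(
    time_min = rep(x$times, each = nrow(x$conc)),
    compartment = rep(rownames(x$conc), times = length(x$times)),
    conc_ng_ml = as.vector(x$conc)
  )
}

#' Steady-state unbound concentration ratios under constant forcing
#'
#' Solves the linear steady state `A x = -b` under unit constant unbound
#' plasma concentration directly (no time stepping) and returns the
#' unbound concentration of every compartment relative to plasma.
#' The `ECF` entry is the model-implied Kp,uu,BBB.
#'
#' @param model `cns_model`.
#' @return named vector of steady-state `Cu,compartment / Cu,plasma`
#'   ratios (`LYS` is total lysosomal over unbound plasma).
#' @export
steady_state_kpuu <- function(model) {
  stopifnot(inherits(model, "cns_model"))
  x <- tryCatch(solve(model$A, -model$b_unit),
                error = function(e) stop("singular CNS system: ",
                                         conditionMessage(e)))
  cf <- .cns_conc_factors(model)
  ratios <- x * as.numeric(cf[.CNS_STATES])
  names(ratios) <- .CNS_STATES
  ratios
}
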