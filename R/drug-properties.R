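# Drug physicochemical and biological property records, and the
# pH- and lipophilicity-dependent quantities the CNS PBPK model consumes:
# Henderson-Hasselbalch neutral fractions, nonspecific intracellular
# binding, and aqueous paracellular permeability.

# ionizable window: sites outside [2, 12] are effectively always
# neutral/ionized at body pH and are excluded from speciation
.PKA_WINDOW <- c(2, 12)

#' Construct a drug record
#'
#' @param name drug name.
#' @param mwt molecular weight (g/mol).
#' @param logp octanol-water partition coefficient (log10).
#' @param pka_acid numeric vector of acidic pKa values (or NULL).
#' @param pka_base numeric vector of basic pKa values (or NULL).
#' @param psa polar surface area (A^2).
#' @param hba,hbd hydrogen-bond acceptor/donor counts.
#' @param fu_plasma fraction unbound in plasma, in (0, 1].
#' @param kpuu_bbb optional unbound brain-ECF/plasma partition coefficient.
#' @param p_trans optional passive transcellular permeability (cm/min);
#'   a required model input, see [estimate_transcellular_permeability()].
#' @param p_para_override optional paracellular permeability override (cm/min).
#' @return object of class `drug_record`.
#' @export
drug_record <- function(name, mwt, logp, pka_acid = NULL, pka_base = NULL,
                        psa = NA_real_, hba = NA_integer_, hbd = NA_integer_,
                        fu_plasma = NA_real_, kpuu_bbb = NULL,
                        p_trans = NULL, p_para_override = NULL) {
  stopifnot(mwt > 0, is.na(psa) || psa >= 0)
  if (!is.na(fu_plasma) && (fu_plasma <= 0 || fu_plasma > 1))
    stop("fu_plasma must be in (0, 1]")
  if (!is.null(kpuu_bbb) && kpuu_bbb <= 0)
    stop("kpuu_bbb must be positive")
  structure(list(name = name, mwt = mwt, logp = logp,
                 pka_acid = as.numeric(pka_acid),
                 pka_base = as.numeric(pka_base),
                 psa = psa, hba = hba, hbd = hbd,
                 fu_plasma = fu_plasma, kpuu_bbb = kpuu_bbb,
                 p_trans = p_trans, p_para_override = p_para_override),
            class = "drug_record")
}

#' Fraction of drug in the neutral species at a given pH
#'
#' Henderson-Hasselbalch speciation with the independent-site
#' approximation for multiprotic drugs: each acidic site contributes
#' `1/(1 + 10^(pH - pKa))`, each basic site `1/(1 + 10^(pKa - pH))`, and
#' the site terms multiply.  Sites with pKa outside [2, 12] are treated
#' as non-ionizable at body pH.
#'
#' @param pH compartmental pH, in [0, 14].
#' @param drug a `drug_record`.
#' @return fraction in (0, 1].
#' @export
fraction_neutral <- function(pH, drug) {
  stopifnot(pH >= 0, pH <= 14)
  acid <- drug$pka_acid[drug$pka_acid >= .PKA_WINDOW[1] &
                        drug$pka_acid <= .PKA_WINDOW[2]]
  base <- drug$pka_base[drug$pka_base >= .PKA_WINDOW[1] &
                        drug$pka_base <= .PKA_WINDOW[2]]
  fn <- 1
  for (pka in acid) fn <- fn / (1 + 10^(pH - pka))
  for (pka in base) fn <- fn / (1 + 10^(pka - pH))
  fn
}

#' Unbound fraction in brain cells
#'
#' Nonspecific intracellular binding is modelled as equilibrium
#' partitioning into the phospholipid fraction of the cell:
#' `fu_cell = 1 / (1 + f_phospholipid * 10^logP)`.
#'
#' @param drug a `drug_record`.
#' @param f_phospholipid phospholipid volume fraction, in [0, 1).
#' @return fraction in (0, 1].
#' @export
unbound_fraction_cells <- function(drug, f_phospholipid = 0.05) {
  stopifnot(f_phospholipid >= 0, f_phospholipid < 1)
  1 / (1 + f_phospholipid * 10^drug$logp)
}

#' Paracellular permeability across a barrier of given width
#'
#' Aqueous diffusivity is taken from the molecular-weight correlation
#' `D_aq = 9.9e-5 * Mwt^-0.453` (cm2/s); permeability is `D_aq / width`
#' converted to cm/min.  A `p_para_override` on the drug record wins.
#'
#' @param drug a `drug_record`.
#' @param width_um barrier width in micrometres.
#' @return permeability in cm/min.
#' @export
paracellular_permeability <- function(drug, width_um) {
  if (!is.null(drug$p_para_override)) return(drug$p_para_override)
  stopifnot(width_um > 0)
  if (!is.finite(drug$mwt) || drug$mwt <= 0)
    stop("molecular weight must be positive")
  d_aq <- 9.9e-5 * drug$mwt^(-0.453)        # cm2/s
  d_aq * 60 / (width_um * 1e-4)             # cm/min
}

#' Placeholder transcellular permeability estimator
#'
#' Passive transcellular permeability is a required per-drug input to the
#' PBPK model; no structure-based prediction is attempted here.  This
#' logP-linear placeholder (`10^(intercept + slope * logP)` cm/min) is
#' provided only so exploratory runs have an order-of-magnitude value,
#' and its coefficients are fully user-tunable.
#'
#' @param drug a `drug_record`.
#' @param intercept,slope coefficients on the log10 scale.
#' @return permeability in cm/min.
#' @export
estimate_transcellular_permeability <- function(drug, intercept = -2.7,
                                                slope = 0.4) {
  10^(intercept + slope * drug$logp)
}

#' Load the packaged drug records
#'
#' Ten small molecules with physicochemical properties, plasma unbound
#' fractions, Kp,uu,BBB values and placeholder transcellular
#' permeabilities, transcribed into `inst/extdata/drugs.json`.
#'
#' @param names optional subset of drug names.
#' @return named list of `drug_record` objects.
#' @export
cns_drugs <- function(names = NULL) {
  raw <- jsonlite::read_json(system.file("extdata", "drugs.json",
                                         package = "cnspbpk", mustWork = TRUE),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  recs <- lapply(raw$drugs, function(z) {
    drug_record(name = z$name, mwt = z$mwt, logp = z$logp,
                pka_acid = unlist(z$pka_acid), pka_base = unlist(z$pka_base),
                psa = z$psa, hba = z$hba, hbd = z$hbd,
                fu_plasma = z$fu_plasma, kpuu_bbb = z$kpuu_bbb,
                p_trans = z$p_trans)
  })
  names(recs) <- vapply(recs, `[[`, character(1), "name")
  if (!is.null(names)) {
    miss <- setdiff(names, base::names(recs))
    if (length(miss)) stop("unknown drug(s): ", paste(miss, collapse = ", "))
    recs <- recs[names]
  }
  recs
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s: Mwt %.4g, logP %.3g, fu,plasma %.3g",
              x$name, x$mwt, x$logp, x$fu_plasma))
  if (!is.null(x$kpuu_bbb)) cat(sprintf(", Kp,uu,BBB %.4g", x$kpuu_bbb))
  cat("\n")
  invisible(x)
}
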