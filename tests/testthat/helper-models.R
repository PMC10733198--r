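# Shared fixtures, built in code at test time.

# canonical 1-compartment IV test model: C(t) = 100 * exp(-0.1 t) after
# a 1000 ng bolus
one_cpt <- function(CL = 1, Vc = 10, fu = 1, ...) {
  plasma_pk_model(CL = CL, Vc = Vc, fu_plasma = fu, ...)
}

two_cpt <- function(CL = 1, Vc = 10, Q2 = 0.5, Vp2 = 20, fu = 1, ...) {
  plasma_pk_model(n_compartments = 2, CL = CL, Vc = Vc, Q2 = Q2,
                  Vp2 = Vp2, fu_plasma = fu, ...)
}

# neutral probe drug (no ionizable sites in the physiological window)
neutral_drug <- function(p_trans = 1e-3, kpuu = 1, logp = 1) {
  drug_record("probe_neutral", mwt = 300, logp = logp, psa = 50,
              fu_plasma = 0.5, kpuu_bbb = kpuu, p_trans = p_trans)
}

# monoprotic base, pKa 9 (lysosomal-trapping probe)
base_drug <- function(p_trans = 1e-3, kpuu = 1) {
  drug_record("probe_base", mwt = 300, logp = 1, pka_base = 9, psa = 50,
              fu_plasma = 0.5, kpuu_bbb = kpuu, p_trans = p_trans)
}

# monoprotic acid, pKa 5
acid_drug <- function(p_trans = 1e-3, kpuu = 1) {
  drug_record("probe_acid", mwt = 300, logp = 1, pka_acid = 5, psa = 50,
              fu_plasma = 0.5, kpuu_bbb = kpuu, p_trans = p_trans)
}

# physiology with uniform pH, no ECF bulk flow, no asymmetry: every
# compartment must equilibrate with plasma
uniform_physiology <- function() {
  phys_override(mouse_physiology(),
                pH_plasma = 7.4, pH_ECF = 7.4, pH_ICF = 7.4, pH_LYS = 7.4,
                pH_CSF = 7.4, Q_ECF = 1e-12)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
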