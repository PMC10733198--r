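---
title: "Predicting mouse brain-ECF pharmacokinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mouse brain-ECF pharmacokinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnspbpk)
```

## The problem

Unbound drug concentration in brain extracellular fluid (brain ECF) is
what most CNS drug targets actually see, but it can only be measured
invasively, by microdialysis, in animals. The steady-state unbound
partition coefficient Kp,uu,BBB — the ratio of unbound brain-ECF to
unbound plasma concentration — summarizes the *extent* of blood–brain
barrier (BBB) transport but says nothing about the *time course*.
`cnspbpk` couples a compartmental description of mouse plasma
pharmacokinetics to a physiologically based model of the mouse CNS so
that full unbound concentration–time profiles in brain ECF (and the
other CNS compartments) can be predicted from three ingredients:

1. a plasma PK model (fitted to data, or taken from the packaged
   per-drug parameter sets),
2. drug physicochemical properties (molecular weight, logP, pKa,
   unbound fractions), and
3. a Kp,uu,BBB value, converted into *asymmetry factors* that encode
   net active transport at the BBB.

No CNS model parameter is estimated from brain data: the CNS side is
fully determined by physiology, drug properties and Kp,uu.

## Model structure

### Compartments and flows

Eight CNS compartments exchange drug as amounts (ng), with unbound
concentrations defined per compartment volume:

* **MV** — brain microvascular blood (well-stirred, 5 µl), refreshed by
  cerebral blood flow `Q_CBF` carrying the unbound plasma concentration
  `Cu,p(t)` (the forcing function) and draining to venous blood (a
  sink: the plasma model already accounts for systemic disposition, so
  no mass is returned to it);
* **ECF** (67 µl) and **ICF** (288 µl) — brain extra- and intracellular
  fluid, exchanging across the brain-cell membrane (`SA_BCM`);
* **LYS** (3.6 µl) — lysosomes inside the cells, pH 5.5;
* **LV → TFV → CM → SAS** — the CSF cascade (lateral ventricles, third
  + fourth ventricles, cisterna magna, subarachnoid space) at CSF flow
  `Q_CSF`, with ECF bulk flow `Q_ECF` entering the cisterna magna and
  the subarachnoid space draining at `Q_CSF + Q_ECF` to a sink.

The BBB connects MV with ECF; the blood–CSF barrier (BCSFB, choroid
plexus) connects MV with the ventricular CSF, its flux split equally
between LV and TFV (configurable via `bcsfb_split`). This topology —
flow routing, the BCSFB split, and the ECF-flow destination — is a
documented reconstruction of the model family's published structure;
each choice is overridable in `cns_model()`.

### Transport terms

Each barrier carries two passive pathways:

* **transcellular**: `CL = P_trans · SA · f_trans`, acting on the
  *neutral* unbound species of the donor compartment
  (Henderson–Hasselbalch speciation at the donor pH, independent-site
  approximation; sites with pKa outside [2, 12] are treated as
  non-ionizable at body pH). This is the mechanism that produces pH
  partitioning and lysosomal ion trapping.
* **paracellular**: `CL = P_para · SA · f_para`, acting on all unbound
  species symmetrically, with `P_para = D_aq / width` and the aqueous
  diffusivity correlation `D_aq = 9.9e-5 · Mwt^-0.453` cm²/s.

Net active transport at the BBB is encoded by multiplying the total
influx clearance by `AF_in` and the total efflux clearance by `AF_out`,
with `AF_in/AF_out = Kp,uu,BBB` and only one side different from 1
(`asymmetry_factors()`; efflux-side scaling for Kp,uu < 1). The factors
scale the *whole* per-direction clearance (transcellular plus
paracellular): scaling only the transcellular part would make the
steady-state ECF/plasma ratio deviate from the prescribed Kp,uu
whenever paracellular flux is non-negligible, defeating the purpose of
the calibration. BCSFB asymmetry factors default to 1 because no CSF
data constrain them.

Intracellular nonspecific binding enters as an equilibrium unbound
fraction `fu_cell = 1/(1 + f_phospholipid · 10^logP)` (fast binding, no
on/off kinetics). Lysosomes exchange with cytosol through `SA_LYS` with
neutral-species-only permeation, which yields the classical trapping
ratio `fn(pH_ICF)/fn(pH_LYS)` at steady state — for a monoprotic base
with pKa 9 this is 49.4, and the simulator reproduces it to well under
1% (it is one of the acceptance checks).

### Passive permeability is an input

`P_trans` (cm/min) must be supplied per drug. The package deliberately
does not predict it from structure: a hidden QSPR would silently
dominate every prediction. For exploration,
`estimate_transcellular_permeability()` provides a clearly-labelled
logP-linear placeholder (`10^(-2.7 + 0.4·logP)` cm/min, coefficients
user-tunable), and the packaged drug records carry values from this
placeholder, flagged as synthetic in `drugs.json`.

## Numerics: exact linear algebra instead of an ODE integrator

Every kinetic system in the package — plasma compartmental models, the
CNS system, and their one-way coupling (plasma block feeding the MV
compartment) — is linear and time-invariant between dose events.
Rather than integrating with an adaptive stiff solver, the package
propagates states exactly with the matrix exponential, implemented via
eigendecomposition (with a Padé/`Matrix::expm` fallback if the
eigenbasis is ill-conditioned). Consequences:

* there is no solver tolerance to tune; accuracy is machine precision,
  verified by mass-balance audits (residuals ≲ 1e-15 relative in the
  test suite, against a required 1e-6);
* stiffness (the CNS system mixes sub-second lysosomal equilibration
  with multi-hour plasma decay) is irrelevant;
* zero-order infusions are handled as piecewise-constant inputs with a
  closed-form particular solution, and cumulative in/outflow integrals
  (for mass balance) come from the same closed form.

Steady states under constant forcing are computed by a direct linear
solve (`steady_state_kpuu()`), not by long simulation; the two agree to
0.1% in the tests.

## Plasma PK: simulation and pooled estimation

Models of 1–3 compartments support IV bolus/infusion and extravascular
dosing with first-order absorption `ka`, optionally preceded by
zero-order release of the dose over a stated duration (the convention
adopted for parameter sets that print both `ka` and a duration).
Extravascular parameter sets that print `ka = 0` (two of the packaged
ten) are treated as instantaneous absorption — the dose enters the
central compartment directly — since a depot with zero rate constant
would trap the dose forever.

Inter-individual variability uses the exponential model
`θ_i = θ · exp(η_i)`, `η_i ~ N(0, ω²)`; residual error is proportional
or combined proportional + additive (`obs = pred(1 + ε_p) + ε_a`).

`fit_plasma_model()` performs *naive-pooled* maximum likelihood on the
typical values: full nonlinear mixed-effects estimation (FOCE/SAEM) is
out of scope, and IIV is used in simulation only. The proportional
error variance is profiled analytically; the reported objective
function value (−2 log L) supports likelihood-ratio comparison of
nested structures with the usual 3.84 criterion, and the test suite
verifies this calibration on 50 null replicates. Two numerical
safeguards matter in practice: a log-scale least-squares fit (bounded,
and exact at a noise-free optimum) seeds the ML optimization, and the
profiled variance is floored at 1e-30 so that noise-free data — where
the proportional-error likelihood is unbounded — remain well-behaved.
Observations flagged below the quantification limit are excluded from
the likelihood, the simplest defensible rule.

## Kp,uu estimation

Two routes, which agree to 1% on noise-free linear systems (a package
invariant):

* **AUC ratio** (`kpuu_from_auc()`): AUC(0–∞) of unbound brain-ECF over
  unbound plasma, each by log-trapezoid plus `Clast/λz` extrapolation;
  `λz` from the last three points with an adjusted-R² ≥ 0.8 safeguard.
* **Clearance ratio** (`estimate_bbb_clearances()`): a sequential fit —
  plasma model fixed, one-compartment whole-brain model
  `dA/dt = CL_in·Cu,p(t) − (CL_out/V)·A` fitted to ECF data by pooled
  ML under proportional error; `Kp,uu = CL_in/CL_out`. The apparent
  brain volume defaults to the ECF volume (67 µl) and is configurable;
  with fast brain equilibration only the clearance *ratio* is well
  identified, which is exactly the quantity consumed downstream.

## Synthetic studies

Because the in vivo datasets behind the packaged parameter sets are not
public, `generate_study()` fabricates complete studies with known
ground truth, emulating their statistical structure: destructive plasma
sampling (default 3 animals per time point) or serial sampling;
brain-ECF microdialysis reported as interval averages over 20-min
collection windows (computed by composite Simpson quadrature, exact for
linear curves); exponential IIV on the plasma parameters; proportional
(+ additive) residual error; probe recovery as a known multiplicative
factor (default 1, i.e. recovery-corrected concentrations). Defaults
were chosen once as representative of sparse mouse PK studies and are
not tuned: real per-study schedules are not reproduced, and a green
synthetic test establishes the correctness of the estimation machinery,
not the field performance of the model.

The "low-noise" closed-loop acceptance check (generate → fit plasma →
estimate Kp,uu → simulate → evaluate against the generating truth) uses
ω²_CL = 0.01 and proportional variance 0.0025 (5% CV) for both
matrices, 8 serial plasma animals and 4 microdialysis animals — small
enough that a correctly closed loop must come back within 120% AAFE,
large enough that the noise paths are genuinely exercised.

## Evaluation metrics

`%AFE = 100·10^(mean log10(pred/obs))` measures bias (100% = unbiased,
symmetric in over/under-prediction); `%AAFE = 100·10^(mean |log10
ratio|)` measures accuracy and is ≥ 100% by construction. Per-drug
fold-error classes use the drug-level geometric statistic
(`10^(mean |log10 ratio|) ≤ k`); the stricter "every point within
k-fold" rule is available via `rule = "all_points"` since the
convention is not standardized. VPC bands are pointwise empirical
percentiles (default 2.5/50/97.5) across simulation replicates on a
common grid. Observed–predicted pairs are matched at identical nominal
times, and BQL points are excluded.

## The physiology registry

The packaged mouse registry stores, for each parameter, the collected
literature values, the aggregation rule (mean; median for total brain
volume), or the derivation from other parameters (ICF = 80% of brain
volume; lysosomes = 1.25% of ICF; BCSFB surface = 50% of BBB surface;
cell-membrane surface from the monodisperse-sphere model
`N·(36π)^{1/3}·(V_ICF/N)^{2/3}`). Units are canonicalized internally to
ml / ml/min / cm / cm² / min / ng.

`validate_physiology()` distinguishes hard violations (non-positive
values, ICF + ECF exceeding total brain volume, fractions outside
(0, 1], implausible pH) from *soft warnings* that surface
inconsistencies deliberately carried over from the source compilation,
which are preserved rather than "fixed":

* the lateral-ventricle volume is stored as the adopted 4 µl although
  the mean of the collected values is ≈ 0.66 µl;
* the CSF sub-volumes (4.8 + 2.13 + 16.88 µl) do not sum to the total
  CSF volume (35 µl);
* lysosomal pH is stored as the adopted 5.5 although the mean of the
  collected values is 5.38;
* the lysosomal surface area (540 cm²) is a literal: the lysosomal
  radius behind it is not available.

## Known limitations

* The CNS equations are a reconstruction: barrier-flux routing and the
  BCSFB split follow the compartment list and published usage of the
  model family, not a verbatim equation set; all are config-overridable.
* Pooled (not mixed-effects) estimation biases parameter estimates
  when IIV is large; the packaged parameter sets are used as fixtures,
  not re-estimated.
* `P_trans` placeholder values make the packaged drug records suitable
  for pipeline exercise, not for quantitative claims about the ten
  drugs.
* No brain metabolism, target binding, transporter saturation, or
  disease-state physiology; plasma protein binding is a constant
  `fu,plasma`.

## A worked steady-state check

```{r steady-state}
phys <- phys_override(mouse_physiology(), Q_ECF = 1e-12)
drug <- cns_drugs("topotecan")[[1]]
model <- cns_model(phys, drug)           # AF from the drug's Kp,uu 0.21
round(steady_state_kpuu(model), 4)
```

The ECF entry reproduces the prescribed Kp,uu (0.21) to within 0.1%
once ECF bulk flow is removed; with physiological `Q_ECF` the small
deviation follows the closed form `CL_in/(CL_out + Q_ECF)` exactly.
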