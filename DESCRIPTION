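Package: cnspbpk
Title: Physiologically Based Pharmacokinetics of Drug Distribution into
    Mouse Brain Extracellular Fluid
Version: 0.1.0
Authors@R:
    person("cnspbpk", "developers", email = "cnspbpk@example.org",
           role = c("aut", "cre"))
Description: A mouse-parametrized central nervous system (CNS)
    physiologically based pharmacokinetic (PBPK) simulator for small
    molecules, driven by compartmental plasma pharmacokinetic forcing
    functions and blood-brain-barrier asymmetry factors derived from
    unbound partition coefficients (Kp,uu,BBB).  Includes a curated mouse
    CNS physiology registry, drug physicochemical records with
    pH-partitioning and nonspecific-binding submodels, compartmental
    plasma PK simulation and pooled maximum-likelihood fitting, Kp,uu
    estimation by AUC and clearance ratios, prediction-error metrics
    (%AFE, %AAFE, fold-error classes, VPC bands), and a synthetic
    microdialysis-study generator with known ground truth.  All kinetic
    models are linear and are solved exactly by matrix exponentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
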