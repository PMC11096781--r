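Package: daptopk
Title: Population Pharmacokinetics of Intravenous Daptomycin in Critical Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of intravenous
    daptomycin in critically ill patients, including patients on continuous
    renal replacement therapy (CRRT). Provides closed-form two-compartment
    kinetics for zero-order infusions, a covariate-structured nonlinear
    mixed-effects model with lognormal inter-individual variability and a
    combined additive/proportional residual error, FOCE-I/Laplace estimation
    with stepwise covariate selection and subject-resampling bootstrap,
    goodness-of-fit and visual predictive check diagnostics, a synthetic
    ICU-cohort generator for simulation studies, and Monte Carlo
    probability-of-target-attainment dose simulations on an AUC24/MIC basis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
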