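Package: dcepbpk
Title: DCE-MRI-Informed Physiologically Based Pharmacokinetic Modelling of
    Antibody Tumor Disposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking dynamic contrast-enhanced MRI (DCE-MRI) kinetic
    parameters to physiologically based pharmacokinetic (PBPK) predictions of
    monoclonal antibody disposition in solid tumors. Provides saturation-recovery
    T1 estimation, spoiled-gradient-echo signal-to-concentration conversion,
    constrained Patlak model fitting with individual arterial input functions, a
    tumor PBPK compartment with FcRn recycling and quasi-equilibrium
    target-mediated drug disposition, covariate models mapping Ktrans and Vp onto
    tumor plasma flow and the vascular reflection coefficient, maximum-likelihood
    population fitting with AIC-based structure selection, a priori per-subject
    prediction for target-binding antibodies, synthetic xenograft cohort
    generation, and evaluation summaries (mean prediction error, tumor-to-plasma
    ratio tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
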