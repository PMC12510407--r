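Package: chpwater
Title: Choroid Plexus Water Density Quantification from Proton Density-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying choroid plexus
    (ChP) water density from high-resolution proton density-weighted MRI by
    white-matter ratio calibration. Provides a closed-form spin-echo signal
    model with a driven-equilibrium (DRIVE) steady-state solution, a
    synthetic periventricular phantom and actigraphy cohort generator with
    Rician noise and known ground truth, ROI-based water-density
    quantification, cosinor rhythmometry of per-minute energy-expenditure
    traces with individual circadian time correction, propagation of
    water-density assumptions into pseudo-continuous arterial spin labeling
    (pCASL) perfusion error, and the repeated-measures statistics (linear
    mixed models with subject random intercepts, epoch contrasts, and rank
    correlations) used to test for time-of-day effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
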