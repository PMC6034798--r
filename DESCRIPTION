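Package: acgtools
Title: Multispectral Transcranial Ultrasound Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for acoustocerebrography
    (ACG), a transcranial transmission-ultrasound technique that
    characterizes brain tissue from the per-frequency time of flight and
    attenuation of a compound multitone pulse. Provides a dispersive,
    attenuating forward signal model; least-squares recovery of component
    amplitudes and phases; phase-based time-of-flight estimation with
    integer-cycle ambiguity resolution; per-exam feature extraction; a
    calibrated synthetic case-control cohort generator; the group
    comparisons used in ACG studies (Fisher's exact test, Kruskal-Wallis);
    and a cross-validated gradient-boosted classifier with ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
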