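Package: methscore
Title: Polyepigenetic DNA Methylation Scores for Smoking Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes polyepigenetic DNA methylation scores from a
    beta-value matrix and a CpG weight table (weighted-product averages of
    methylation fractions, cohort-standardized), and provides the analyses
    used to validate such scores as smoking biomarkers: group contrasts and
    ROC discrimination, pack-year dose-response, family-clustered (GEE)
    estimation, twin intraclass correlations with Falconer and
    maximum-likelihood ACE variance decomposition, between/within twin-pair
    effect decomposition, two-wave change analyses (quit/continue
    trajectories, dependence contrasts, change-on-change regression),
    probe-wise EWAS with covariate-adjustment attenuation comparison, and a
    stratified methylation-expression correlation screen with cis/trans
    annotation. A seeded synthetic-cohort generator emulates the
    statistical structure of smoking-methylation cohort data so every
    analysis is exercisable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
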