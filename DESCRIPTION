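Package: stumpwave
Title: Intraoperative Carotid Stump Pressure Waveform Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of intraoperative internal carotid artery (ICA) stump
    pressure recordings acquired during carotid endarterectomy: zero-phase
    low-pass and Savitzky-Golay conditioning, cardiac cycle mapping with a
    second-derivative anacrotic fiducial, two-step correlation-gated ensemble
    averaging, pulse-wave morphometrics (amplitudes, durations, areas and the
    area-method diastolic decay constant of a two-element Windkessel), ICA to
    systemic pressure ratios, a rule-based circle of Willis variant
    classifier, and the cohort statistics layer (one-way ANOVA, Tukey HSD,
    Pearson/Spearman correlation, chi-square/Fisher tests). A Windkessel-type
    pulse-trace and cohort simulator with analytic ground truth makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
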