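Package: visualcvid
Title: VISUAL Multianalyte Prognostic Score for Common Variable
    Immunodeficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the VISUAL score, a five-analyte prognostic point score
    for common variable immunodeficiency (CVID) built from switched-memory
    B-cell percentage, serum IgA and IgM, specific antibody responses to
    polysaccharide and protein vaccines, and CD4+ T-cell counts at diagnosis,
    together with the validation pipeline used to assess it: Ameratunga and
    Grimbacher clinical severity scoring with two-cluster dichotomization and
    silhouette diagnostics, ROC analysis with the closest-to-(0,1) optimal
    cutpoint, paired McNemar and bootstrap classifier comparisons, logistic
    and Fisher-exact association statistics, Kaplan-Meier progression curves
    with the Mantel-Cox log-rank test, and a synthetic cohort generator that
    emulates the published cohort structure so every stage is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
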