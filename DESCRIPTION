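Package: cohortcompare
Title: Two-Cohort Somatic Landscape, Immune and Clonality Comparison for
    Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the computational stages
    behind an Asian-versus-Caucasian breast cancer cohort comparison:
    a somatic variant post-calling filter cascade with panel-of-normals
    and cohort-recurrence rules, 20/20-style oncogene and tumour-suppressor
    scoring, pairwise mutual-exclusivity analysis, refitting of per-sample
    mutational-signature exposures over a 13-signature breast catalogue,
    single-sample immune scoring (rank-enrichment and IMPRES-style
    checkpoint features), expression-based oestrogen-receptor calling via a
    two-component Gaussian mixture, cancer-cell-fraction and intratumour
    heterogeneity metrics, and population-level prevalence and survival
    statistics. A synthetic two-cohort generator with known ground truth
    makes every stage testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    survival,
    pracma,
    generics,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
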