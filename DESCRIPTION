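Package: tpodr
Title: Transcriptomic Points of Departure from Dose-Response Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns short-term dose-series gene-expression count matrices into
    gene-level benchmark doses (BMDs), gene-set-level transcriptomic points of
    departure (TPODs), and TPOD-versus-apical-POD concordance summaries.
    Implements low-count filtering, CPM normalization, linear-model batch
    adjustment, an ANOVA/fold-change prefilter, a nine-model continuous
    dose-response suite (exponential, linear, polynomial, Hill, power) fitted
    by constant-variance maximum likelihood, benchmark-dose inversion at a
    1.349-standard-deviation benchmark response, one-sided 95%
    profile-likelihood confidence bounds (BMDL/BMDU), Fisher's exact gene-set
    enrichment, and potency/concordance comparisons against apical
    NOAEL/LOAEL/NOEC/LOEC tables. Includes a synthetic-data generator with
    known per-gene ground truth so the full workflow is testable without any
    external download.
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
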