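Package: devswitch
Title: Detecting Developmental Switches Between Similar Gene Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects developmental "switches" between functionally
    interchangeable gene variants (e.g. receptor subunits) in
    developmental transcriptome cohorts. Candidate pairs are drawn from
    pathway-element co-membership and filtered by global protein-sequence
    similarity; life-long anti-correlated expression trends are screened
    per brain region with an expression-range filter and FDR control; and
    subject-to-subject co-fluctuation is quantified by an age-corrected
    (spline-detrended residual) correlation, a nonlinear analogue of the
    partial correlation given age. Includes permutation null models, a
    housekeeping-gene baseline, and a synthetic-cohort generator with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
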