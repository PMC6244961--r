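Package: hlasab
Title: Cross-Platform Analysis of HLA Single-Antigen-Bead Antibody Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Luminex single-antigen-bead (SAB) HLA
    antibody data across vendor bead panels and secondary detection
    antibodies. Implements background normalization of trimmed-mean MFI,
    positivity calling, classification of conformational HLA class I
    variants (intact trimer, peptide-free heterodimer, beta2-microglobulin
    free heavy chain) from three-monoclonal-antibody panel characterisation,
    common-antigen concordance statistics between vendor panels with exact
    paired nonparametric tests, expansion of positive beads into
    unacceptable-antigen lists, calculated panel-reactive antibody (cPRA)
    engines with a Monte Carlo donor-sampling oracle, and a mechanistic
    simulator of the full two-panel by two-secondary-antibody experiment
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    vctrs,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
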