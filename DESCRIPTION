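Package: chaperoscope
Title: Chaperome Expression Profiling, M-Scores and Interactome Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative profiling of chaperome deregulation in
    tumor-versus-normal expression cohorts. Implements Gene Set Analysis
    with the maxmean statistic, sample permutation and gene-set
    restandardization summarised as signed delta-GSA scores; Meta-PCA, a
    two-step dimension reduction that averages sign-aligned per-tissue
    first principal components into universal family weight vectors and
    per-sample M-scores; differential-expression fractions of chaperome
    functional subsets; evidence-level curation of physical
    protein-protein interactions with PSI-MI ontology up-propagation into
    single-evidence, multiple-evidence and multiple-method tiers; and
    family meta-networks with force-directed layouts, polar summaries and
    interactome-guided topographic surfaces. Ships a synthetic cohort and
    interaction-corpus generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
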