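Package: pathstrat
Title: Pathway-Utilization Stratification of Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies bulk expression cohorts by pathway utilization rather
    than marker genes. Each sample is ranked against the cohort mean and scored
    for every gene set of a collection by preranked gene set enrichment
    analysis with a permutation-normalized enrichment score; the resulting
    sample-by-set enrichment profile feeds principal-component contribution
    analysis to synthesize directional gene signatures, Monti-style consensus
    clustering (with an NMF alternative and a random-forest robustness check),
    Kaplan-Meier/log-rank survival comparison with multiplicity correction,
    per-cell signature scoring with dual-diagonal correlation maps,
    coexpression-module and hub-gene discovery, differential expression,
    overrepresentation analysis, and limiting-dilution frequency estimation.
    A synthetic-data generator plants recoverable cluster, survival and
    single-cell structure so the full pipeline is testable without external
    cohorts.
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
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
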