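Package: workseq
Title: Life-Course Work-Schedule Sequence Analysis and Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for charting longitudinal work-schedule trajectories and
    linking them to later health. Builds fixed-length categorical state
    sequences (not working, standard daytime, evenings, nights, other
    nonstandard, missing) from long-format person-year panels, computes
    optimal-matching dissimilarities by the Needleman-Wunsch dynamic program
    with transition-rate (TRATE) substitution costs, clusters sequences with
    Ward's hierarchical method and Duda-Hart / Calinski-Harabasz stopping
    indices, profiles and labels the resulting trajectory clusters, and
    estimates cluster-health associations on standardized outcomes via OLS and
    logistic regression with SD-unit effect sizes. Includes a synthetic panel
    generator with known latent trajectory classes so the full pipeline is
    testable without restricted survey microdata.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    sandwich,
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
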