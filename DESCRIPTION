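Package: restmeg
Title: Resting-State MEG Spectral, Connectivity and Brain-Cognition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for source-level resting-state MEG
    analysis in cohort studies: scalar minimum-variance beamforming, automatic
    epoch quality scoring and selection, periodogram spectral features
    (relative band power in six canonical bands, individual alpha peak
    frequency), leakage-corrected amplitude-envelope connectivity (AECc),
    covariate-adjusted group statistics with effect sizes and
    Benjamini-Hochberg false-discovery-rate control, resting-state-network
    aggregation of effects, and partial-least-squares correlation between
    brain and cognitive or cognitive-reserve variables with permutation and
    bootstrap inference.  A synthetic-data module generates oscillatory
    source recordings, forward models and cohort tables with planted,
    recoverable ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
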