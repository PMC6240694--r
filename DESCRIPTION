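Package: dosenet
Title: Weighted Gene Co-Expression Networks for Dose-Response Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed, soft-thresholded Spearman co-expression networks
    from dose-response expression experiments and detects gene modules via
    topological overlap and dynamic tree cut. Supports calibrated consensus
    networks across exposure conditions, module eigengene-dose correlation
    statistics, transcription-factor target-set enrichment by Fisher's exact
    test with Benjamini-Hochberg adjustment, and hub-gene identification that
    combines intramodular connectivity (kME) with degree in an external
    interaction network. Includes a synthetic-data generator that plants
    dose-responsive modules, regulator target sets and interaction edges, with
    ground truth for scoring module recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
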