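Package: laminatad
Title: Lamina-Associated Chromatin Domain Analysis and Polymer Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how nuclear-lamina disruption reshapes
    chromatin architecture in Drosophila. Implements iterative correction
    (ICE) of binned Hi-C contact maps, expected-by-distance and
    observed/expected transforms, gamma-scaled dynamic-programming TAD
    calling with a two-step large-domain split and small-domain merge,
    average-contact-frequency (ACF) statistics with replicate-concordance
    filtering, LAD/active-chromatin composition and Jaccard-based TAD
    grouping, A/B compartment annotation by principal components with
    saddle-plot aggregation, LAD-aware binned-track fold-change analysis,
    and a dissipative-particle-dynamics simulator of a sticky block
    copolymer at an attractive surface with reversible saturating bonds.
    A synthetic-data module generates contact maps, annotations and tracks
    with planted structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    withr
Config/testthat/edition: 3
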