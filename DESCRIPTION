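Package: barcogeo
Title: Integrative Species Delimitation from DNA Barcodes, Geography and
    Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting species from single-locus DNA barcode data
    together with collection geography and discrete morphological characters.
    Implements Kimura two-parameter (K2P) pairwise distances with pairwise
    deletion, recursive barcode-gap partitioning over a scan of prior
    intraspecific divergences with plateau-based partition selection,
    single-linkage geographic delimitation of populations within
    morphospecies across a distance-threshold scan, neighbour-joining trees
    with bootstrap and per-cluster monophyly assessment, and congruence-based
    species validation under the generalized lineage concept, including
    detection of morphologically cryptic species. A seeded simulator
    generates barcode datasets with planted species truth for calibration
    and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
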