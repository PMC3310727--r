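Package: polytile
Title: Tiling-Array Analysis of Polycomb Occupancy and H3K27me3 Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window peak calling for ChIP-chip tiling arrays under a
    Gaussian background model estimated from mirrored negative log-ratios,
    with strand-aware peak-to-gene assignment, TSS-aligned metagene matrices
    and k-means High/Low clustering, co-occupancy classification of genes by
    repressor binding and H3K27me3 status (Group I/II), tiling-array
    transcription scores with standard-deviation-based differential calls,
    and Poisson/Fisher category-enrichment statistics. Includes a synthetic
    tiling-array generator with planted domains and full ground truth so the
    whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
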