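Package: hicblocks
Title: Block-Processed Extraction, Merging and Aggregation of Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for querying binned chromatin contact matrices stored in the
    cooler dialect (.cool/.mcool HDF5 containers). Pixels and regular or jagged
    submatrices are pulled across many files at once with a block-processing
    engine that bounds working memory by the size of one genome block, and
    results are kept in HDF5-backed arrays with random access by interaction.
    Downstream methods cover density-based (DBSCAN) merging of redundant loop
    calls with full metadata provenance, loop enrichment scores against a
    customizable local background, and aggregate pileups: aggregate peak
    analysis (APA), rescaled aggregate domain (TAD) plots and boundary-centered
    pileups. A deterministic simulator generates contact maps with power-law
    distance decay, planted loops and domains, multiplicative per-bin biases
    with matching balancing weights, and jittered replicate loop-call files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
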