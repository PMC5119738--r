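Package: spikechip
Title: Spike-In Normalization for ChIP-Seq with an Exogenous Reference
    Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Normalization of ChIP-seq experiments that undergo global
    occupancy changes, using a second-species chromatin spike-in
    precipitated by a species-specific antibody.  Reference-species tag
    counts (whole-genome or restricted to pre-defined reference regions)
    yield per-sample correction factors that rescale experimental-species
    libraries by seeded random tag removal.  Includes the standard tag
    filters (duplicate removal, mapping-quality cutoff, 3'-extension,
    binned coverage), a broad-domain island caller with a Poisson
    background model and Monte-Carlo E-value threshold, per-region signal
    quantification across conditions, spike-in design arithmetic, and a
    two-species library simulator with a controlled global fold change
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
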