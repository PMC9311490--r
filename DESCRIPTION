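Package: alleleHub
Title: Allele-Specific Nascent Transcription Simulation and Quantification Under a Shared Limiting Pol II Hub
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates allele-specific MS2/PP7 live-imaging traces of nascent
    transcription in early Drosophila embryos under a two-state (telegraph)
    promoter model in which both homologous alleles of a nucleus draw
    initiating RNA polymerase II from a single shared, finite hub pool.
    Provides trace quantification (activity calling, onset, duration,
    amplitude, area-under-curve RNA production), dorsoventral expression-domain
    analysis, genotype comparison statistics with embryo-level bootstrap
    confidence intervals, and a synthetic-movie renderer with matched nuclei
    segmentation, spot detection and trace extraction for end-to-end
    validation of the quantification pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    data.table,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
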