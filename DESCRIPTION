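Package: rejuvsig
Title: Aging and Rejuvenation Gene Signatures from Bead-Array Detection Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for deriving presence/absence gene signatures
    of cellular aging and rejuvenation from Illumina-style bead-array data.
    Implements negative-control-based detection p-values, background
    correction and quantile normalization, detection-call signature
    extraction (expressed in induced mesenchymal stromal cells and
    pluripotent cells but absent in parental MSCs, and the mirror aging
    rule), differential expression with Storey q-value FDR control and
    ratio-based up/down calls, delta-delta-Ct relative quantification,
    protein-association network construction from BioGRID-style interaction
    tables with top-interactor augmentation and Girvan-Newman
    edge-betweenness community detection, and cytokine-array membrane
    densitometry with reference-spot normalization.  Ships synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    ape,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
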