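Package: hictrio
Title: Integrative Trio Hi-C and Transcriptome Analysis of Hybrid Heterosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for parent/parent/hybrid (trio) studies that
    combine chromosome conformation capture (Hi-C) with RNA-seq to dissect
    heterosis. Provides contact-matrix input/output and iterative-correction
    balancing, distance-decay expected models, A/B compartment calling by
    principal component analysis of the observed/expected correlation matrix
    with gene-density orientation, trio compartment-shift classification,
    directionality-index TAD calling with conserved/specific comparison and
    activated/repressed classification, expression-side statistics (active
    genes, specifically expressed genes, trio DEG categories, mid-parent and
    high-parent heterosis), integration of expression changes with structural
    changes into a candidate-gene list, and a synthetic trio generator with
    recorded ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
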