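Package: genedomains
Title: Gene-Anchored Contact Domain Calling from High-Resolution Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies fine-scale chromatin contact domains whose boundaries
    coincide with gene borders (single-gene domains, multigene domains, and
    differentially insulated genes) from binned Hi-C contact matrices at
    sub-kilobase resolution. Distance-normalized (observed/expected) contact
    frequencies inside gene-anchored target regions are compared against
    diagonal-equidistant control regions with rank tests under
    Benjamini-Hochberg false discovery rate control. Also provides structural
    analytics over called domains (rescaled pile-up aggregation,
    directionality index, compartment eigenvector, Jaccard reproducibility)
    and a synthetic Hi-C simulator with planted domains for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
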