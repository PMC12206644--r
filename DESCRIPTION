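Package: tregfp
Title: Bidirectional Molecular Fingerprinting for Regulatory T Cell Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene-set enrichment (ssGSEA) scoring of bidirectional
    gene signatures for quality control of regulatory T cell (Treg) cell-therapy
    products. Computes identity (Treg vs effector T cell) and expansion
    (day-14 vs day-0) fingerprint scores as the difference between a positive
    and a negative sub-score, classifies samples at a zero threshold, derives
    signatures from differential-expression tables by thresholding and
    cross-dataset intersection, evaluates classifier performance and
    suppression-assay statistics, and simulates synthetic bulk RNA-seq cohorts
    with planted identity, expansion, and activation-confounded genes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
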