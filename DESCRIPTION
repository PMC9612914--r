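Package: mnscaling
Title: Power-Law Relationships Between Spinal Motoneuron Properties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives and validates quantitative power-law relationships
    between morphometric and electrophysiological properties of spinal
    alpha-motoneurons from heterogeneous per-study datasets. Implements
    percent-of-maximum normalization, pooled log-log regression, the
    iterative size-transformation and merging algorithm that references
    every property to motoneuron size, fivefold cross-validation of the
    fitted relationships, scaling of normalized relationships to absolute
    SI units through empirical and theoretical fold ranges, Rall
    equivalent-cylinder cable quantities, generation of inter-consistent
    motoneuron property profiles and pools, muscle-unit coupling
    exponents, and a synthetic-corpus generator with known ground truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
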