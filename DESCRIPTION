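Package: epigp
Title: Genomic Prediction with Non-Additive Effects via NOIA Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction in livestock populations when
    non-additive genetic effects (dominance and epistasis) are of interest.
    Builds marker codings under the natural and orthogonal interactions (NOIA)
    parameterisation, constructs trace-scaled additive, dominance and
    Hadamard-product epistatic relationship matrices (including an exact
    pairwise additive-by-additive construction), estimates variance components
    for multi-kernel linear mixed models by average-information REML with EM
    fallback, and evaluates models by stratified cross-validation and
    subsampling stability analyses. A synthetic-data module simulates paternal
    half-sib genotype panels with tunable linkage disequilibrium and
    phenotypes with additive, dominance (optionally directional) and
    additive-by-additive architectures, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
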