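Package: famdel
Title: Family-Based Evaluation of Structural Deletion Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation machinery for structural-deletion call sets in
    family-based whole-genome sequencing studies. Implements the D-score,
    a sibling-sharing log-likelihood-ratio statistic for caller specificity;
    spike-in sensitivity estimation under reciprocal-overlap matching;
    KING-robust kinship calibration of call-set genotype quality; a quality
    control cascade built around a one-sided Hardy-Weinberg
    excess-heterozygosity exact test; a family segregation rule for candidate
    variants; and a pedigree/call-set simulator with Hardy-Weinberg founders,
    Mendelian transmission, genotype-specific caller sensitivities and both
    random and locus-reproducible false-positive calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
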