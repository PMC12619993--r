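Package: gocsma
Title: Genomic Optimum Contribution Selection and Mate Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage optimization for genomic breeding programs.
    Stage one solves optimum contribution selection (maximize mean
    offspring breeding value subject to a quadratic genomic coancestry
    constraint and per-sex contribution sums) with an ADMM conic
    operator-splitting solver using a second-order-cone reformulation of
    the coancestry bound. Stage two allocates matings among the selected
    parents by minimizing contribution-weighted coancestry as a binary or
    integer linear program, solved exactly by branch-and-bound over a
    transportation-structured relaxation. Includes VanRaden method-1
    genomic relationship matrices with minor-allele-frequency filtering,
    future-coancestry and genetic-gain evaluation of mating plans,
    truncation-selection and random-mating baselines, and a reproducible
    synthetic SNP-panel generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
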