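Package: paraconv
Title: Indels from Nonallelic Gene Conversion Between Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phylogenetic detection and analysis of insertions and deletions
    produced by nonallelic gene conversion between paralogs. Classifies
    conversion-consistent, fixed, and ordinary-mutation indels from triplet
    alignments of paralog pairs (two sister species and an outgroup) by
    parsimony, estimates per-site conversion rates with a Poisson
    multiple-hit correction, quantifies deletion bias with exact binomial
    sign tests and length stratification, computes rank correlations with
    genomic covariates, models the cooperative shrinkage of paralogs under
    deletion-biased conversion, and provides a forward simulator of
    paralog-pair coevolution on a three-taxon tree with a complete
    ground-truth event log for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
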