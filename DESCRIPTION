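Package: bsmask
Title: Double-Masking of Bisulfite Sequencing Alignments for Conventional Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bisulfite treatment converts unmethylated cytosines to thymines,
    so whole-genome bisulfite sequencing (WGBS) alignments confound true C/T
    (and G/A) polymorphisms with chemistry-induced mutations. bsmask implements
    the "double-masking" preprocessing procedure that rewrites WGBS alignments
    so that conventional Bayesian variant callers can consume them: read bases
    in a bisulfite-convertible context are replaced by the reference base at
    aligned reference-C/read-T (reference-G/read-A) mismatches, and the base
    quality of every potentially converted base is set to zero, imposing an
    indirect strand-specificity on variant evidence. The package also provides
    a synthetic diploid WGBS read simulator with CG/CHG/CHH methylation
    contexts, in silico bisulfite conversion of conventional reads and
    alignments, a minimal Bayesian diploid genotyper with MAPQ/BQ hard
    filtering, and precision/sensitivity/F1 benchmarking against truth
    variants with score-threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    withr
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
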