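Package: clonocomp
Title: Pairwise Statistical Comparison of Immune-Repertoire Clonotype Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical comparison of two immune-repertoire (IG or TR)
    clonotype sets per V, D, and J gene and allele from amino-acid clonotype
    tables. Implements the standardized pairwise difference-in-proportions
    procedure (two-proportion z-test with an exact-test fallback for small
    occurrences), seven multiple-testing adjustments (Bonferroni, Holm,
    Hochberg, Sidak single-step and step-down, Benjamini-Hochberg,
    Benjamini-Yekutieli), rejection-count curves and volcano-style scatter
    tables, per-10,000 normalization and locus-ordered synthesis tables,
    CDR length distributions, IMGT-unique-numbering position profiles of
    amino acids and amino-acid classes with Shannon, Wu-Kabat and Simpson
    variability indices, V-D-J gene-association contingency tables with
    double Ward clustering, and a synthetic-repertoire generator for
    calibration and power benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
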