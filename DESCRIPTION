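Package: tecnet
Title: Cross-Species Co-Expression Networks of Transposable Elements and
    KRAB Zinc-Finger Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing transposable-element (TE) subfamily and
    gene expression across species and conditions from bulk RNA-seq count
    matrices. Implements a scaling-factor normalization that calibrates
    the empirical type I error of an exact binomial equality test on
    conserved features, negative-binomial differential expression with
    configurable fold-change thresholds, all-pairs gene-by-TE Pearson
    correlation with Benjamini-Hochberg control and leave-one-out
    consensus, permutation nulls against random gene sets and
    binding-evidence pair lists (Jaccard overlap), evolutionary-age
    classification of correlation links, bipartite network analysis with
    Barber modularity and module enrichment, and cross-species /
    control-versus-disease link contrasts. A synthetic-data generator
    with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
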