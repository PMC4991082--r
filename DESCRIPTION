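Package: dielnet
Title: Diel Rhythm Detection and Network-Based Prediction of Rhythmic Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 24 h diel rhythms in temporal gene expression data with a
    nonparametric Jonckheere-Terpstra-Kendall scan against cosine-derived
    orderings (exact null distributions, Benjamini-Hochberg q-values, cosinor
    fits), builds gene co-expression networks under five construction schemes
    (signed/absolute Pearson correlation and mutual information with top-K edge
    budgets and intersections), predicts additional rhythmic genes from node
    centrality profiles (including graphlet degree centrality) and from Markov
    clustering with randomized nulls, and predicts gene-function associations by
    guilt-by-association with leave-one-out validation. Ships a synthetic-data
    generator that emulates a 12-timepoint, 4-replicate light:dark microarray
    design with bimodal peak phases and module-structured co-expression, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
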