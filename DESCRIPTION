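Package: habvar
Title: Phylogenetic Comparative Analysis of Climatic Niche Breadth and
    Gene Functional Categories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores species' climatic niche breadth (a climate-envelope
    statistic counting occupied cells of a grid over the first two principal
    components of the 19 bioclim variables, and Brillouin diversity of
    habitat climate classes), derives genomic predictors (duplicated-gene
    counts from all-vs-all homology hit tables and per-category gene counts
    against a functional catalogue), and relates the two with a phylogenetic
    comparative inference chain: Felsenstein's independent contrasts,
    cross-validated LASSO screening on contrasts, phylogenetic generalized
    least squares under Brownian-motion covariance, all-subsets AICc model
    selection, and multimodel averaging over the 95% confidence set with a
    significance gate. A synthetic-data generator emulates a complete
    mammalian study (tree, traits, climate samples, homology hits, gene
    function maps) so every stage and the full pipeline can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
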