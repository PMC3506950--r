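Package: phylofun
Title: Phylogeny-Aware Metagenome Inference and Sparse Multivariate
    Association for Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers community gene (KEGG ortholog) content from 16S
    phylotype relative abundances by mapping taxonomy clades onto an
    annotated reference phylogeny (Jaccard overlap of descendant genomes)
    and reconstructing ancestral gene-content vectors as branch-length
    weighted averages of descendant leaf genomes.  Screens microbial
    features (clades, genes, gene sets) for associations with mixed-type
    sample metadata using per-feature boosted covariate selection followed
    by a linear model on arcsine-square-root transformed abundances, with
    within-factor Bonferroni and global Benjamini-Hochberg multiplicity
    control.  Includes the quality-control filters the analysis assumes
    (low-abundance/prevalence, missingness, outer-fence outliers,
    imputation), alpha-diversity metrics (inverse Simpson, Chao1, Pielou),
    and a synthetic-data generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    vegan,
    jsonlite
Config/testthat/edition: 3
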