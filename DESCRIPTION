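Package: wwsignal
Title: Detecting Treated-Wastewater Perturbation Signals in Mesocosm
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for detecting and characterising a
    treated-wastewater perturbation in mesocosm community metatranscriptomes.
    Implements signal-to-noise-ratio (SNR) detection on Bray-Curtis
    dissimilarities (control-treatment versus control-control distances per
    timepoint, with Welch t, exact Mann-Whitney and PERMANOVA support),
    negative-binomial differential abundance with a treatment-by-time design
    and Benjamini-Hochberg filtering, KEGG-ortholog-to-pathway aggregation
    with prevalence filtering, temporal log2 fold-change trajectory
    clustering with median lines and per-feature SSE, taxa-cluster Pearson
    correlation, and hypergeometric pathway enrichment. A synthetic mesocosm
    generator (negative-binomial counts under temporal effect archetypes)
    provides ground-truth data for every stage.
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
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    DESeq2,
    knitr,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
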