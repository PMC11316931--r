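Package: hologuild
Title: Holo-Omics Functional Groups and Causal Inference for Host-Microbiome Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying rumen (or other host-associated) microbial
    functional groups from multi-layer omics data (metatranscriptome,
    metaproteome, metabolome) and for probing their causal relationship with a
    host phenotype such as feed efficiency. Implements two-group differential
    feature testing (Wilcoxon rank-sum with Benjamini-Hochberg control),
    Fisher-exact functional enrichment with quartile-wise z-score clustering,
    functional-group construction and comparison (Venn counts, Sankey link
    export, Bray-Curtis PERMANOVA/PERMDISP with log2(pseudo-F/q) effect
    sizes), a mixed-model genome-wide association scan for omics features
    (EMMA-style REML with a P3D marker scan), two-sample Mendelian
    randomization with five estimators (IVW, MR-Egger, weighted median,
    simple and weighted mode), and linear mediation analysis with bootstrap
    inference. A synthetic-cohort generator with a known ground-truth ledger
    (SNPs -> taxon -> mediators -> phenotype) makes every stage testable
    without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
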