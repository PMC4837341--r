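Package: cpminet
Title: Component-Protein-Metabolite Interaction Networks for Drug Target
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for network-analysis-based drug target identification
    of multi-component preparations such as traditional herbal formulas.
    Builds a component-target interaction network from molecular-docking
    scores (filtered against per-protein positive-control cutoffs) and
    curated text-mining evidence, a confidence-filtered protein-protein
    interaction layer, and a metabolite-pathway-protein network from
    metabolomics pathway enrichment; integrates the layers into a
    component-protein-metabolite interaction network (CPMI) and
    prioritizes targets that connect active components to metabolite
    biomarkers by path reachability. Also provides the surrounding
    computations: physicochemical descriptors and chemical-space PCA,
    drug-likeness comparison by Kolmogorov-Smirnov and rank-sum tests,
    Tanimoto fingerprint similarity screening, hypergeometric
    over-representation analysis, percentage inhibition of TNF-alpha
    mediated cytotoxicity, and steady-state 1:1 binding affinity fitting,
    plus a seeded synthetic-fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
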