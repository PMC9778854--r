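Package: driftmeta
Title: Population Genomics of Dynamic Metapopulations with Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how extinction-recolonization dynamics shape
    molecular evolution in pond metapopulations of cyclical parthenogens such
    as Daphnia magna. Includes a forward-in-time simulator of partially clonal
    populations under a distribution of fitness effects, a propagule-model
    metapopulation simulator that emits synthetic pool-seq variant and
    covariate tables, Nei-Gojobori synonymous/nonsynonymous site counting,
    pool-seq diversity (pi, piN, piS) and differentiation (FST) estimators
    with read-depth corrections, McDonald-Kreitman alpha and rates of
    (non)adaptive substitution (omega_A, omega_NA), and the ecological
    association stage linking diversity and differentiation to subpopulation
    age and isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    Biostrings,
    rtracklayer,
    geosphere,
    vegan,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
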