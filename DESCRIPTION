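Package: soilpem
Title: Soil Phosphorus, Ecoenzymatic Stoichiometry and Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term fertilization field studies of
    soil bioavailable phosphorus and the microbiome. Provides ecoenzymatic
    stoichiometry vector analysis (vector length and angle, nutrient
    limitation classification), one-way ANOVA with Duncan's multiple range
    letter grouping, alpha and beta diversity with NMDS ordination, Spearman
    co-occurrence network inference with modularity and Zi-Pi keystone
    classification, Mantel permutation tests and taxa-environment correlation
    panels, random-forest permutation importance, partial least squares path
    modelling (PLS-PM) with bootstrap inference, and a seeded synthetic-data
    generator emulating a five-treatment by four-replicate field design so
    every stage is testable without field data.
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
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
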