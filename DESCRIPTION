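Package: ogcurator
Title: Orthogroup Curation and Diagnostics for Phylogenomic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for curating single-copy orthogroups
    before phylogenomic inference. Screens gene trees for long terminal
    branches and for strongly supported violations of clan (order-level)
    monophyly, ranks genes by a substitution-saturation regression slope,
    trims gap-rich alignment columns and concatenates survivors into a
    partitioned supermatrix with parsimony-informative site counts.
    Companion diagnostics include posterior-predictive adequacy statistics
    for amino-acid site diversity and across-taxon compositional
    heterogeneity, gene concordance and discordance factors against a
    reference species tree, pairwise Ka/Ks rate summaries under the
    Nei-Gojobori (1986) estimator, and Fisher-exact detection of conserved
    macrosynteny blocks with chromosome fusion and fission calling. A
    seeded synthetic-data generator plants each artifact class with truth
    labels so every filter can be benchmarked end to end.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
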