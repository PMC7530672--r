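Package: mlgpop
Title: Microsatellite Multilocus Genotype Metapopulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of diploid microsatellite multilocus genotypes from
    structured (meta)populations, built around the workflow used for vineyard
    and cellar Saccharomyces cerevisiae surveys: genotype table import with a
    missing-data admission rule, clone correction within strata, Bruvo genetic
    distance and neighbor-joining trees, minimum spanning networks, genotype
    diversity indices with rarefaction and Chao1 extrapolation, hierarchical
    AMOVA with Phi statistics and permutation tests, pairwise Fst, Mantel
    isolation-by-distance tests, relative directional migration from Jost's D,
    attribution of isolates to commercial starter strains by allele sharing,
    and a forward-time stepwise-mutation island-model simulator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    withr
Config/testthat/edition: 3
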