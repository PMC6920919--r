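Package: phyllonet
Title: Seasonal Phyllosphere Community Structure and Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-structure analysis of seasonal phyllosphere and air
    16S rRNA OTU tables: singleton and taxon filtering, rarefaction to a
    common depth, alpha diversity (Shannon, Simpson, Pielou) with paired
    seasonal comparisons, abundant/rare and Levins niche-breadth
    generalist/specialist classification, Bray-Curtis group-average
    clustering with SIMPER decomposition of within- and between-group
    (dis)similarity, and Maximal Information Coefficient (MIC) co-occurrence
    networks characterised by Cytoscape-style topological parameters against
    Erdos-Renyi G(n,m) random-graph nulls. Includes a synthetic community
    generator with planted generalist/specialist roles for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    vegan,
    igraph,
    ape,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
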