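Package: strataseq
Title: Habitat-Stratified Sample Subsetting and Morphospecies
    Prioritisation for Reference-Database Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the StrataSeq workflow for cost-efficient generation
    of DNA reference databases for hard-to-identify, species-rich taxa:
    habitat-stratified subsetting of samples along environmental gradients
    (region, soil type, land-use intensity), occupancy-ranked prioritisation
    of morphospecies with stop-rules, scheduling of detailed morphological
    identification across maximally distinct habitats, and gap analysis
    against molecular reference catalogues. Ships the benchmarking
    arithmetic (taxon overlap, effort ratios, abundance-weighted individual
    coverage, coverage-effort curves), the accompanying community statistics
    (Bray-Curtis dissimilarity, PERMANOVA with sequential sums of squares,
    non-metric multidimensional scaling, richness ANOVA), and a synthetic
    community simulator with occupancy-abundance coupling so the whole
    workflow can be exercised and stress-tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
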