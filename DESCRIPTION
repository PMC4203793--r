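Package: micropart
Title: Two-Part Differential Abundance Analysis for Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S rRNA amplicon surveys of microbial
    communities: sliding-window quality trimming and filtering of reads,
    aggregation of taxonomic assignments into sample-by-taxon count tables,
    a two-part presence/abundance test for zero-inflated relative-abundance
    data with prevalence filtering and false discovery rate control,
    Kruskal-Wallis screening across treatment groups, centered log-ratio
    principal component ordination, and random-forest taxon importance
    ranking.  Includes a Dirichlet-multinomial community simulator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Biostrings,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
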