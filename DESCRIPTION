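Package: shadowForest
Title: Shadow-Feature Random Forest Selection of Treatment-Sensitive
    OTUs in Microbiome Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies bacterial operational taxonomic units (OTUs) whose
    abundance responds to a two-group dietary intervention in 16S rRNA count
    data. The core method extends random-forest variable importance with
    shadow features (randomly permuted copies of every OTU): forests are
    refit repeatedly with fresh shadows, and each OTU's relevance likelihood
    is the one-sided Welch t-test of its importance against the strongest
    shadow, giving an empirical null gate against spurious selection.
    Supporting stages cover OTU-table rarefaction, relative abundance,
    taxonomic aggregation and multi-trial pooling, generalized UniFrac beta
    diversity on a rooted phylogeny, principal-coordinates ordination,
    one-factor PERMANOVA, phylum-level abundance-shift reporting, and a
    synthetic community generator that plants treatment-sensitive OTUs with
    known direction so the whole pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
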