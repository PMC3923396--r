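Package: wheatgerm
Title: Time-Course Microarray Analysis of Seed Germination with
    Profile Clustering and Network Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reusable pipeline for short time-course
    expression studies of the kind used to profile wheat seed
    germination on Affymetrix-style arrays. Provides MAS 5.0-style
    probe-set summarization (Tukey biweight signal, Wilcoxon detection
    calls, trimmed-mean scaling), random variance model (RVM) moderated
    one-way ANOVA with permutation-based false discovery rates,
    STEM-style model-profile temporal clustering with an exhaustive
    time-point permutation test, hierarchical clustering and
    functional-category aggregation, pathway enrichment with
    pathway-interaction (path-net) construction, KEGG-style gene
    signal-net degree ranking, and Pearson co-expression networks with
    k-core decomposition. A seeded synthetic-data generator plants
    flat genes, temporal profiles, co-expression modules and enriched
    pathways so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
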