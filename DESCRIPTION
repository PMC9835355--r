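Package: comscope
Title: Community Metabolic Networks from Annotated Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs community-level metabolic networks from annotated
    shotgun-metagenome gene tables and simulates their activity. Provides
    count-table binning under taxonomic and functional annotation keys with a
    contig-taxonomy majority rule, two-group differential abundance testing
    (TMM normalization with a conditional negative-binomial exact test),
    Simpson-index scoring of taxonomic dominance over enzymatic functions,
    directed metabolite-graph construction from a KEGG-like reaction bank,
    prediction of environmental resources (seed compounds) via
    strongly-connected-component condensation, network-expansion simulation of
    the producible-compound scope, in-silico taxa knock-outs yielding
    taxa-dependent compounds, and hypergeometric pathway enrichment with FDR
    control. A synthetic-data generator with planted ground truth allows the
    whole pipeline to run and be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
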