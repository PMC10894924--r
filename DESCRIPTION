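Package: stimnet
Title: Stimulus-Response Co-Expression and Regulatory Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how a clinical covariate
    (e.g. diastolic blood pressure) modulates per-patient transcriptional
    responses to an acute stimulus such as lipopolysaccharide. From paired
    baseline/stimulated log2 expression matrices it builds a per-patient
    log2 fold-change response matrix, detects weighted co-expression modules
    (soft-threshold adjacency, topological overlap, hierarchical clustering,
    eigengenes), associates modules with clinical traits, learns a bootstrapped
    Bayesian consensus network over module summaries and the trait, infers a
    mutual-information regulatory network with data-processing-inequality
    pruning and signed modes of regulation, scores per-patient transcription
    factor activities by analytic rank-based regulon enrichment, calls hub
    genes by robust rank aggregation of five network centralities, and screens
    a drug-signature library with a weighted bidirectional Kolmogorov-Smirnov
    connectivity score. A synthetic-cohort generator with planted ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
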