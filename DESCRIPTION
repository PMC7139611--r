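Package: counterflow
Title: Integrated miRNA/mRNA Counter-Expression Analysis of Oxidative
    Stress Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for integrating miRNA and mRNA
    differential-expression data with miRNA-target predictions.
    Compiles oxidative-stress gene sets by reverse Gene Ontology
    lookup (from GO terms to their annotated genes), aggregates
    per-algorithm miRNA-target predictions into a consensus target
    map, validates predicted targets by counter-expression (miRNA and
    target changing in opposite directions in the same contrast),
    characterizes the validated set by hypergeometric GO enrichment
    with Benjamini-Hochberg FDR and by a bipartite miRNA-gene network
    with Barber-modularity community detection, and analyzes qPCR
    validation data by the comparative Ct (delta-delta-Ct) method
    with Mann-Whitney rank-sum tests.  Includes a synthetic-data
    generator with planted ground truth so the whole workflow is
    testable end to end, and packaged reference fixtures from a
    published atherosclerosis-progression study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
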