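Package: potatonet
Title: Co-Occurrence Metanetworks and Treatment Analytics for
    Multi-Location Microbiome Field Trials
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analytics for multi-location agricultural
    microbiome trials with a control/treated design sampled at two
    timepoints. Builds signed presence-absence co-occurrence and
    co-exclusion metanetworks from rarefied amplicon count tables using a
    hypergeometric pair test with false discovery rate control, extracts
    per-sample local network properties (Louvain modularity, transitivity,
    average path length), performs location-standardized Wilcoxon and
    Kruskal-Wallis treatment tests, Spearman association networks across
    microbiome indexes, yield and physicochemical variables, ordination
    (Bray-Curtis, PCoA), PERMANOVA, envfit-style vector fitting,
    location-centered redundancy analysis, core-microbiome prevalence
    profiling, location-constrained shared-taxa counts, and negative
    binomial differential abundance. Includes a synthetic multi-location
    trial generator with planted, recoverable effects so the entire
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
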