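Package: prionscape
Title: Proteome-Wide Detection and Systems Characterization of Prion-Like Proteins
Version: 1.0.0
Authors@R:
    person("prionscape", "developers", email = "prionscape@example.org",
           role = c("aut", "cre"))
Description: Tools for the in-silico characterization of prion-like proteins
    in a proteome. Implements a two-stage prion-like domain (PrLD) caller
    combining a compositional log-likelihood-ratio scan with best-21-mer
    amyloid-core scoring on a 0-100 scale (acceptance cutoff 60), terminal
    localization statistics under a 25/50/25 sequence segmentation, generic
    term enrichment (Fisher's exact test, Bonferroni correction, log-ratio
    enrichment scores), ordinal tissue-expression deviation-vector clustering
    with silhouette-based model selection, and resampling-based significance
    for disease association and interactome proximity (largest connected
    component and mean shortest distance against random-set nulls). Ships a
    synthetic-data generator that plants known PrLDs, term enrichments,
    expression clusters, disease-rate differences and network modules so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
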