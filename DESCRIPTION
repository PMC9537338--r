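Package: avcycle
Title: Cell-Cycle State and Arterial-Venous Fate Scoring for Endothelial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links endothelial cell-cycle state to arterial-venous identity in
    transcriptomic data. Derives FUCCI cell-cycle-state gene signatures from
    bulk RNA-seq of sorted reporter populations (one-way ANOVA on log2-CPM with
    Benjamini-Hochberg control), scores single cells for cell-cycle state,
    TGF-beta/BMP signaling and arterial-venous identity using expression-bin-
    matched module scores and diffusion-based imputation (powering of a
    row-stochastic kNN Markov operator), and quantifies score associations by
    simple linear regression, one-way ANOVA with Tukey HSD, and Welch t-tests.
    Ships a seeded negative-binomial simulator of FUCCI-sorted bulk and
    arterial-venous continuum single-cell data so the full analysis is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
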