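Package: DecayCoupling
Title: Coupled Divergence of mRNA Degradation and Transcription in Yeast
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates mRNA degradation rates from transcription-arrest time
    courses (global rescaling to an assumed genome-wide decay, per-probe
    log-linear fits with a goodness-of-fit gate, probe-to-gene aggregation),
    calls inter-species and inter-allele differential degradation, decomposes
    transcription-rate divergence as TR = D x L, quantifies opposite coupling
    between degradation and transcription divergence, classifies divergence
    into cis and trans effects using interspecific-hybrid allele data, tests
    regulator target-set enrichment of coupled genes, and calls diverged
    transcription-factor binding sites in orthologous promoters by PSSM
    log-odds scanning. Ships a fully synthetic two-species-plus-hybrid
    experiment generator with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    fgsea,
    rlang
Suggests:
    testthat (>= 3.0.0)
biocViews: Transcriptomics, GeneExpression, GeneRegulation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
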