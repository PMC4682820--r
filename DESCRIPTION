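Package: renalage
Title: Transcription-Factor Drivers of the Kidney-Aging Transcriptome
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying transcription-factor drivers of
    age-related gene expression in the human kidney. Implements a
    complexity-filtered ChIP-seq target-enrichment screen (promoter-window
    peak-to-gene assignment, HOT-region filtering, Fisher/chi-square overlap
    tests with Bonferroni correction and a specificity control), per-gene
    age and GFR expression regression with coefficient-attenuation analysis,
    cytokine-response direction-concordance and profile-correlation
    statistics, per-sample transcription-factor activity scoring from
    target-gene z-scores with macrophage-marker covariation, and a
    candidate-gene SNP analysis with allelic odds-ratio reconstruction from
    summary statistics by chi-square matching. A synthetic-data generator
    emulates the statistical structure of the study inputs so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
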