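Package: agesplit
Title: Separating Primary Aging from Inflammation- and Inactivity-Driven
    Expression Changes in a Three-Group Multi-Omics Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a three-group (young healthy,
    young patient, older patient) multi-omics workflow that separates
    "primary aging" gene-expression changes from changes driven by chronic
    inflammation and physical inactivity.  Provides negative-binomial Wald
    differential expression with median-of-ratios normalization and
    TPM/fold-change/FDR gates, simulation-based power analysis, TMT
    proteome batch normalization with one-way ANOVA and Tukey-Kramer
    post-hoc tests, protein-mRNA concordance classification,
    direction-consistent primary-aging gene selection, trajectory z-scores,
    promoter PWM scanning in the TRANSFAC text format, and
    transcription-factor binding-site enrichment via confidence-corrected
    odds ratios (adjusted fold enrichment) against sampled non-DE background
    promoters.  A synthetic-data module generates all inputs with planted
    ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
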