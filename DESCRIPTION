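Package: secretoMiner
Title: Curation and Marker Discovery for Differential Cell Secretomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to curate differential cell-secretome protein tables into
    high-confidence secreted biomarkers and to characterise them downstream.
    The curation funnel applies fold-change and p-value thresholds, excludes
    proteins without gene symbols, averages multiple protein IDs per gene,
    requires direction concordance across conditions, restricts candidates to
    a tissue-specific proteome, and calls a secretion class from a consensus
    of signal-peptide predictors plus SecretomeP scores. Downstream modules
    provide hypergeometric over-representation with Benjamini-Hochberg
    correction, miRNA-target by transcription-factor cross-referencing with
    direction-consistency explanations, cluster-mean miRNA scoring with
    subtype-stratified Pearson correlation, two-group expression comparison,
    and expression-cutoff Kaplan-Meier survival with log-rank testing. A
    synthetic-data generator emulates every input with planted ground truth
    so the whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
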