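Package: isousage
Title: Differential Transcript Isoform Usage Between Breast Cancer Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of subtype-specific transcript isoform usage from
    transcript-level abundance matrices and gene models. Identifies genes
    whose isoform usage differs between estrogen-receptor-positive and
    triple-negative breast tumours via subtype-by-isoform interaction
    ANOVA with Storey q-value FDR control, classifies the structural
    mechanism behind each differential isoform pair (exon skipping,
    intron retention, alternative donor/acceptor, alternative promoter
    and 3'UTR usage), normalizes NanoString-style probe counts with a
    negative-binomial model, transfers a logistic subtype classifier
    across platforms with ROC evaluation, and quantifies overlap between
    knockdown-responsive and subtype-specific isoform sets with exact
    contingency statistics. Includes a fully seeded synthetic-data
    generator with known ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: MASS, limma, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
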