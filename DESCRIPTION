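Package: trialsig
Title: Two-Stage Phase II Trial Inference and Transcriptomic Response Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact machinery for single-arm Simon two-stage binomial trials:
    exhaustive optimal/minimax design search, operating characteristics,
    conditional-error recalibration of the final decision boundary under
    attained (under-enrolled) sample sizes, and design-consistent inference
    (stagewise-ordering p-values and confidence intervals) on the observed
    response count. Alongside the design engine, a bulk-transcriptomic
    response-signature pipeline: library-size normalisation, empirical-Bayes
    moderated-t gene ranking between clinical-benefit groups, preranked
    gene-set enrichment with leading-edge extraction, cross-arm leading-edge
    intersection to derive a resistance signature, rank-based and z-score
    single-sample signature scoring, and association of scores with clinical
    benefit and progression-free survival (AUC, rank tests, Spearman,
    Kaplan-Meier / log-rank / Cox). Synthetic trial and expression-cohort
    generators provide a fully self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
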