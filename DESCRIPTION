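Package: oasig
Title: Consensus Transcriptomic Signatures, Drug Repositioning and Risk
    Scores for Osteoarthritis Cohort Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting a consensus differential-expression
    signature from heterogeneous osteoarthritis transcriptomic cohorts by
    Fisher-combination meta-analysis, for prioritizing signature-reversing
    drugs in pathway space (pathway-based expression profiles and two-set
    pathway set enrichment analysis) together with protein-protein
    interaction network proximity of signature genes to drug targets, and
    for building a patient-level risk score by bootstrapped elastic-net
    stability selection benchmarked against a full-signature ridge score
    via ROC/AUC and the DeLong test. Includes seeded synthetic-data
    generators that emulate the statistical structure of the study
    cohorts so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    limma,
    Matrix,
    stats,
    utils
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
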