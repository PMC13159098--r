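Package: histoscale
Title: Bi-Scale Gene Expression Prediction from Histology Patch Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene expression from whole-slide-image patch embeddings
    at both tissue (bulk) and near-cellular (spot) resolution. A gated causal
    linear recurrence fuses ordered patch-embedding sequences, a learnable CLS
    token aggregates a whole-slide summary, and separate MLP heads emit
    spot-level and slide-level expression predictions. Training proceeds in
    two stages (scale-specific pretraining, then joint bi-scale fine-tuning
    with a convex loss-mixing weight), with patient-wise cross-validation and
    a dual-criterion early-stopping rule. Includes expression normalization
    (TPM/CPM/pseudo-bulk), slide tiling and tissue filtering, an
    image-predictable gene-panel selector, per-gene evaluation metrics, a
    bulk-spot expression similarity AUC, downstream risk-score and
    differential-expression utilities, and a synthetic paired-cohort
    generator with a known embedding-to-expression mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
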