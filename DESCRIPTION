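Package: tcrcontact
Title: Explainable TCR-pMHC Binding Prediction with Contact Prototype Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts T cell receptor (TCR) binding to peptide-MHC complexes
    from per-residue embeddings of the CDR3 alpha, CDR3 beta and peptide
    sequences, and explains each prediction with residue-level contact maps.
    A cross-attention feature-fusion stage mixes the three sequences, and a
    differentiable contact-prototype head converts pairwise embedding
    similarity into thresholded contact areas whose mean is the binding
    score, so the explanation is the prediction rather than a post-hoc
    attribution. Includes dataset utilities (shuffled negative sampling,
    unseen-epitope splits by Levenshtein distance), a precompute-and-cache
    embedding store with pluggable providers, a deterministic training loop
    with analytic gradients, evaluation metrics (partial ROC-AUC under a
    false-positive-rate cap, Binding Region Hit Rate against
    structure-derived residue distances, center-aligned contact-map
    averaging), and a synthetic benchmark with planted contacts that makes
    both discrimination and explanation recovery measurable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
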