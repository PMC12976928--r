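# tcrcontact

Explainable prediction of TCR-pMHC binding from residue-level sequence
embeddings, with contact maps as the explanation.

## The problem

Whether a T cell receptor (TCR) recognizes a peptide-MHC complex is
determined largely by residue contacts between the CDR3 loops of the TCR α
and β chains and the presented peptide. Supervised predictors of this
interaction are usually black boxes: they output a probability but no
testable account of *which residues* drive it. `tcrcontact` implements an
explain-by-design head for this problem: per-residue embeddings of CDR3α,
CDR3β and peptide (from any external protein language model) are mixed by
six directed cross-attention blocks, and a differentiable contact-prototype
head converts pairwise cosine similarity into thresholded contact areas

    S = clamp(cos, 0, 1) / max(τ, 1)            similarity map
    M_i = σ((S − t_i)·N)                        contact filter at threshold t_i
    A' = (1/|T|) Σ_i softmax(T)_i · M_i         aggregated contact area
    w  = (1/N²) Σ_{k,j} A'_{kj}                 contact score per chain
    ŷ  = (w_a + w_b)/2                          binding score

so the explanation (`A'`, one map per chain, peptide rows × CDR3 columns)
and the prediction are the same object. Training minimizes class-weighted
binary cross-entropy with analytic gradients (compiled RcppArmadillo
kernels, with a pure-R reference implementation tested for exact
agreement).

The package also provides the surrounding workflow: dataset reading and
validation, shuffled negative sampling at a configurable ratio,
unseen-epitope train/test splits with an exhaustive Levenshtein guarantee,
a precompute-and-cache embedding store with a pluggable provider interface,
partial ROC-AUC (FPR ≤ 0.1, McClish-standardized), the Binding Region Hit
Rate (BRHR) against structure-derived nearest-atom residue distances (PDB
via bio3d), center-aligned contact-map averaging, and a fully
self-contained synthetic benchmark with planted contacts.

## Worked example

A complete run on the synthetic benchmark — generate a world with a planted
contact rule, train, score a held-out draw, and check both prediction and
explanation quality:

```r
library(tcrcontact)

world <- generate_world(seed = 42)         # planted contacts + codebook
train <- generate_dataset(world, n_pos = 400, neg_ratio = 4, seed = 101)
test  <- generate_dataset(world, n_pos = 100, neg_ratio = 4, seed = 202)

seqs  <- unique(unlist(rbind(train$records, test$records)[
  c("cdr3a", "cdr3b", "peptide")]))
store <- build_store(seqs, synthetic_provider(world))

fit <- contact_model(train$records, store = store,
                     epochs = 45, learning_rate = 1e-4, seed = 1,
                     score_norm = "valid", dropout = 0)
print(fit)

pred <- predict_dataset(test$records, store, fit, maps = TRUE)
partial_auc(pred$scores$y_hat, test$records$label, max_fpr = 0.1)

i  <- which(test$records$label == 1)[1]
dv <- distance_vectors(test$distance_maps[[i]])
brhr(residue_importance(pred$map_a[[i]], axis = "tcr"),
     dv$cdr3a_to_pep, t = 0.25)
```

Running exactly this script prints

```
Explainable TCR-pMHC contact model

Call:
  contact_model(data = train$records, store = store, epochs = 45,
    learning_rate = 1e-04, seed = 1, score_norm = "valid", dropout = 0)

2000 records (400 positive, 1600 negative), pos_weight 4
45 epoch(s); final train loss 2.3857, val loss 2.2534; tau = 1
```

with a held-out partial ROC-AUC of `0.8644737` (chance is 0.5 under the
McClish standardization) and, for the first positive record, a BRHR of
`0.5` at `n_selected = 4` of `L = 15` CDR3α residues: half of the model's
top-ranked quarter of loop residues are also among the structurally
closest quarter. Averaged over all held-out positives and all four
residue directions the BRHR is about 0.59 — 2.3× the random-ranking null
of 0.25 — so the model recovers the planted contact rule, not just the
labels. (Binding scores live on the 0.001–0.1 scale by construction — the
head's aggregated area is bounded by 1/|T| — so they are ranking scores,
not calibrated probabilities; see the methods vignette.)

Fitted models support the usual verbs: `print`, `summary`, `coef`,
`predict` (scores or full contact maps), `plot` (loss curves or
center-aligned class-average contact maps), `residuals`, `simulate`.

A thin command-line front end over the same functions is installed at
`inst/cli/tcrcontact.R` (`simulate`, `embed`, `train`, `predict`,
`explain`).

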