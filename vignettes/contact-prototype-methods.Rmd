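---
title: "Explainable TCR-pMHC binding with contact prototype layers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable TCR-pMHC binding with contact prototype layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcontact)
```

## The problem

T cell receptors (TCRs) recognize short peptides presented by MHC molecules.
Specificity is dominated by the hypervariable CDR3 loops of the alpha and
beta chains, which make direct residue-residue contacts with the peptide.
`tcrcontact` predicts whether a paired-chain TCR (CDR3α + CDR3β) binds a
given peptide, starting from per-residue embeddings of the three sequences
produced by any external protein language model (PLM), and — unlike a black
box classifier — returns, for every prediction, residue-level contact maps
that *are* the prediction: the binding score is the mean of the estimated
contact area, so the explanation cannot disagree with the output.

## The model

Let $E_a, E_b, E_e \in \mathbb{R}^{N\times d}$ be the padded residue
embeddings of CDR3α, CDR3β and the peptide ($N$ = padded maximum length,
$d$ = embedding dimension; padding rows are zero).

**Feature enhancement and fusion.** Six directed single-head cross-attention
blocks mix the chains. Writing $A(Q{=}x, K{=}V{=}y)$ for scaled dot-product
attention with learned projections $W_q, W_k, W_v$ and a residual
connection,

$$E_{a\to b} = A(Q{=}E_a, K{=}V{=}E_b), \qquad
  E_{b\to a} = A(Q{=}E_b, K{=}V{=}E_a),$$

then the peptide is fused with each first-stage output in both directions:
$E_{e \to a b} = A(Q{=}E_e, KV{=}E_{a\to b})$,
$E_{ab \to e} = A(Q{=}E_{a\to b}, KV{=}E_e)$, and the analogous pair
through $E_{b\to a}$. Row $k$ of each output corresponds to residue $k$ of
the query sequence, so the first pair carries (peptide rows, CDR3α rows)
and the second (peptide rows, CDR3β rows).

**Contact prototype head.** For a fused pair $(E_1, E_2)$ the head models
contact through similarity:

$$S_{kj} = \frac{\max(\cos(E_{1,k}, E_{2,j}),\, 0)}{\max(\tau, 1)}
  \in [0,1],$$

with a trainable temperature $\tau = \mathrm{softplus}(\tau_{raw}) > 0$.
A bank of $|T|$ fixed thresholds $t_i = i/(|T|{+}1)$ filters the map
differentiably, $M_i = \sigma\!\big((S - t_i)\,N\big)$, the filtered maps
are combined with softmax area weights $A = \mathrm{softmax}(T)$,

$$A' = \frac{1}{|T|}\sum_i A_i\, M_i \in [0,1]^{N\times N},$$

and the scalar contact score is the mean area
$w = \tfrac{1}{N^2}\sum_{k,j} A'_{kj}$. The prediction for a TCR-pMHC pair
is the mean of the two chain scores, $\hat y = (w_a + w_b)/2$, and $A'$
itself is the explanation: `residue_importance()` reduces it along either
axis (maximum by default, mirroring the nearest-atom convention of
structural ground truth) to rank residues.

**Loss.** Training minimizes class-weighted binary cross-entropy
$-[w_+\, y \log \hat y + (1-y)\log(1-\hat y)]$ with $\hat y$ clamped to
$[10^{-7}, 1-10^{-7}]$; the positive-class weight defaults to the
negative:positive ratio of the training set (4 for the canonical 4:1
negative sampling).

### A structural note on the score scale

Because the area weights sum to one, $A' \le 1/|T|$ everywhere, so with
$|T| = 10$ and $N=25$ the score $\hat y$ of a record with typical lengths
cannot exceed roughly $0.02$ — far below $1$. The cross-entropy therefore
never calibrates $\hat y$ as a probability; it acts as a monotone ranking
loss, and all evaluation is rank-based (ROC). This matches the reported
behaviour of the approach, where average contact scores of binders and
non-binders differ on the $0.01$–$0.10$ scale. Two consequences shaped the
design below.

## Design choices in the open parts

The literature on this head leaves several pieces unstated; the package
fixes them as follows.

* **Similarity range.** Cosine similarity lives in $[-1,1]$ but the
  similarity map is asserted to be in $[0,1]$: negative cosines are clamped
  to zero before the temperature division, and the effective divisor is
  $\max(\tau,1)$ so the codomain claim holds for any $\tau$; $\tau$ starts
  at $1$. Zero-norm rows get similarity 0 rather than an error.
* **Threshold bank.** $|T| = 10$ evenly spaced thresholds $i/11$, fixed
  (not trained), so the softmax area weights are constants. Both $|T|$ and
  the values are configurable.
* **Attention block.** One single-head scaled-dot-product block per
  directed arrow with separate $W_q, W_k, W_v$ ($d\times d$, no biases), a
  residual connection, and dropout 0.2 on the attention output during
  training. There is deliberately **no post-normalization**: the contact
  head consumes cosine geometry, and a trainable normalization layer after
  the residual both erases the norm information carried by the embeddings
  and admits a degenerate optimum in which a shared learned offset aligns
  all rows (every cosine $\to 1$, every record identical — we observed
  exactly this collapse with a standard post-LayerNorm block under the
  imbalanced, range-limited loss above). $W_v$ is initialized at a tenth of
  the $W_q/W_k$ scale so each block starts near the identity and the fused
  embeddings initially preserve the raw embedding geometry.
* **Chain labelling.** The CDR3α map is the prototype applied to the pair
  whose TCR axis consists of α-chain query rows,
  $f(E_{e\to ab}, E_{ab\to e})$, and likewise for β — i.e. maps are named
  by the chain whose residues form their TCR axis.
* **Weight tying.** The α- and β-side arrows are untied by default; a tied
  mode (shared parameters per fusion stage) exists and makes the model
  exactly equivariant under chain swap, which the tests exploit.
* **Score normalization.** $w$ divides by $N^2$ ("maximum possible contact
  area") by default, exactly as the score is defined. Because the number of
  valid cells then scales $w$ with sequence length, an optional
  `score_norm = "valid"` mode divides by $L_1 L_2$ instead, removing the
  length confound; the synthetic benchmark below trains in this mode and
  the flag is recorded in checkpoints.
* **Training regimen.** AdamW (lr $10^{-3}$, weight decay $10^{-2}$ on
  projections only), batch size 512, 150 epochs, global gradient-norm
  clipping at 1.0 (the sigmoid filters have slope $N$ and can produce sharp
  gradients), 10% of training epitopes held out for checkpoint selection by
  validation loss. Fixed seeds make runs bit-reproducible; the analytic
  backward pass is verified against central finite differences and the
  compiled (RcppArmadillo) and reference R engines are tested for exact
  agreement.

## Dataset handling

Records are (CDR3α, CDR3β, peptide, label) triplets. Sequences are
uppercased before validation (public TCR datasets mix cases) and rows with
characters outside the 20 standard one-letter codes are dropped with a
reported count. Negatives are generated per epitope by moving a donor
record's *paired* chains onto the target epitope's peptide at a
configurable ratio (floor of ratio × positives per epitope; 4:1 by
convention), rejecting collisions with known positives with a bounded retry
count. Unseen-epitope splits select test epitopes whose minimal Levenshtein
distance to every other epitope exceeds a threshold; the guarantee is
re-verified exhaustively on every split.

## Evaluation

* **Partial ROC-AUC** restricted to FPR $\le 0.1$, McClish-standardized so
  chance is 0.5 and a perfect classifier 1.0; ties are collapsed into
  single ROC vertices and the cap is handled by linear interpolation. At
  `max_fpr = 1` it reduces to the full AUC.
* **Binding Region Hit Rate (BRHR)** compares, per residue direction, the
  top $t$ fraction of residues ranked by model contact score with the top
  $t$ fraction ranked by structural proximity;
  $k = \max(1, \lceil t L \rceil)$ guarantees at least one contact residue
  and $t = 0.25$ is the default. Ground-truth distances come either from
  the synthetic generator or from PDB structures via `residue_distances()`
  (nearest-atom rule, hydrogens excluded, altloc A preferred).
* **Center-aligned averaging** re-places each map's valid block centrally
  in the padded frame before averaging, so maps of different lengths can be
  summarized jointly by predicted class.

## The synthetic benchmark

Real embeddings and structures are large external dependencies, so the
package ships a fully self-contained world in which both discrimination
and explanation recovery are measurable offline:

* a **residue codebook** (rank-8 factorization of a drawn low-rank latent
  structure — residue chemistry is low-dimensional) whose clamped pairwise
  cosine *defines* the 20×20 compatibility table, so the planted signal is
  exactly the geometry the embeddings realize in the noise-free limit;
* a **contact template**, one fixed set of (peptide position, CDR3
  position) pairs per chain. The default is the full core interface —
  every pair within the guaranteed minimum lengths (8 peptide × 10 CDR3
  positions), as in a compact loop-on-peptide interface where every core
  residue has a nearby partner; sparse templates (`n_contacts`) are
  available for study. The full block matters twice over: it makes the
  label equal (up to noise) to the quantity the head's aggregate genuinely
  estimates, and it makes the per-residue proximity ground truth
  content-determined, which is the only kind of explanation a
  position-blind similarity head can in principle recover;
* **sequences** with sparse Dirichlet residue composition
  (`composition_alpha = 0.25`): each peptide or loop uses a biased residue
  palette of a handful of amino acids, as real epitopes and CDR3 loops do.
  The bias couples a triplet's core-interface compatibility to its overall
  compatibility (record-level signal) while leaving enough within-sequence
  diversity for residues of one record to be meaningfully ranked against
  each other (explanation-level signal); the two requirements pull in
  opposite directions and the default sits between them;
* **labels** by thresholding `signal_strength` × (standardized mean
  core-interface compatibility) + standard normal noise at the quantile
  matching the negative:positive ratio, so the unconditional positive rate
  is $1/(1+\text{ratio})$ and `signal_strength = 0` severs any
  sequence-label dependence. The default `signal_strength = 6` was set by
  a ceiling analysis — large enough that the standard-normal label noise
  is a small fraction of the latent variance, so Bayes-optimal ranking and
  the embedding-cosine oracle both clear the recovery bar with margin and
  the planted rule is recoverable in principle, not just on a lucky draw;
* **distance maps**: template cells of positives get contact-scale
  distances (3–5 Å), linearly decreasing in residue compatibility — the
  model's own premise that compatibility means proximity — while all other
  cells are non-contacts (8–20 Å).

What the generator does *not* emulate: MHC restriction, V/J recombination
statistics, repertoire frequencies, realistic length/positional contact
geometry, or PLM-specific embedding structure. Passing the benchmark shows
the implementation can recover a planted residue-contact rule end to end;
it does not certify performance on real repertoires.

### Benchmark scale and expected results

The standard recovery experiment trains on 400 positives + 1600 shuffled
negatives and evaluates on a disjoint draw of 100 positives + 400 negatives
from the same world. Its training configuration differs from the
large-data defaults in three deliberate ways:

* `score_norm = "valid"` — with variable sequence lengths the $N^2$
  normalizer makes $w$ scale with the number of valid cells, a pure length
  confound on a ranking task;
* `dropout = 0` — the synthetic embeddings already carry i.i.d. Gaussian
  noise and train/test come from the same world, so there is no
  generalization gap for dropout to close, only signal to destroy;
* a short, slow schedule (45 epochs at learning rate $10^{-4}$) — with
  2,000 records the imbalanced bounded-output loss slowly drags all scores
  toward the ceiling once the ranking signal is exhausted (the collapse
  pressure described above in miniature), so the budget stops on the flat
  part of the held-out metric curve rather than training to the 150-epoch
  large-data default.

The degradation companion runs a 3-point `signal_strength` grid down to
zero at reduced size (120 positives, same regimen) and checks that both
metrics fall toward chance (0.5 / 0.25) as the signal vanishes; template
distances interpolate between compatibility-driven and idiosyncratic with
the latent signal fraction $s/\sqrt{s^2+1}$ precisely so that sham
positives at $s=0$ have unpredictable contacts.

## Numerical notes and degenerate inputs

Softmax rows are max-shifted before exponentiation; an all-zero valid query
row yields uniform attention over valid keys. The clamp at cosine 0 and the
$\max(\tau,1)$ divisor are handled with subgradients (gradient zero on the
inactive side); $\hat y$ leaving the clamp interval contributes zero
gradient. Padded rows are never computed on at all (kernels crop to valid
lengths), which makes padding inertness exact rather than approximate; maps
are re-padded for presentation. Top-$k$ selections break ties by ascending
residue index for determinism.

## Known limitations

* The score ceiling $1/|T|$ means $\hat y$ is a ranking score, not a
  calibrated probability; threshold-based decisions need a held-out
  calibration step.
* Single-head, depth-1 attention per arrow; multi-head or deeper variants
  are out of scope.
* The MHC molecule is never consumed; peptides presented by different
  alleles are indistinguishable to the model.
* Real-PLM embedding providers are intentionally out of the test surface;
  only the provider interface and the synthetic provider are exercised.
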