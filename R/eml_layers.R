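# Explainable model layers: cross-attention feature fusion, contact
# prototype head, and the class-weighted loss.
#
# Public functions operate on embedding_block objects and return padded
# N x N explanation maps; the cropped internal forward/backward kernels used
# by the training loop live in autograd.R.

#' Build a fixed bank of contact thresholds
#'
#' The contact-prototype head filters the similarity map at `|T|` thresholds
#' `t_i` in \[0,1\] and weights each filtered map by the softmax of the
#' threshold values (larger thresholds, i.e. shorter implied distances,
#' receive slightly larger area weights). The bank is fixed, not trained.
#'
#' @param n Number of thresholds.
#' @param thresholds Optional explicit strictly increasing vector in \[0,1\];
#'   default evenly spaced `i/(n+1)`, `i = 1..n`.
#' @return Object of class `threshold_bank` with fields `thresholds` and
#'   `area_weights` (softmax of the thresholds, summing to 1).
#' @export
threshold_bank <- function(n = 10L, thresholds = NULL) {
  t <- thresholds %||% (seq_len(n) / (n + 1))
  if (any(t < 0 | t > 1)) stop("thresholds must lie in [0,1]")
  if (any(diff(t) <= 0)) stop("thresholds must be strictly increasing")
  structure(list(thresholds = t, area_weights = softmax(t)),
            class = "threshold_bank")
}

#' @export
print.threshold_bank <- function(x, ...) {
  cat("<threshold_bank> |T| =", length(x$thresholds), "\n")
  cat("  t:", signif(x$thresholds, 3), "\n")
  cat("  A:", signif(x$area_weights, 3), "\n")
  invisible(x)
}

.new_arrow <- function(d) {
  # Wv starts small so each block is near-identity: the fused embeddings
  # initially preserve the raw embedding geometry that the cosine-based
  # contact head consumes, and attention refines it during training
  list(Wq = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
       Wk = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
       Wv = matrix(stats::rnorm(d * d, sd = 0.1 / sqrt(d)), d, d))
}

ARROW_NAMES <- c("ab", "ba", "eab", "abe", "eba", "bae")
TIED_PAIRS <- list(c("ab", "ba"), c("eab", "eba"), c("abe", "bae"))

#' Initialize model parameters
#'
#' One single-head scaled-dot-product cross-attention block (separate Q/K/V
#' projections and a residual connection; no post-normalization, which would
#' erase the embedding norms and directions the cosine-based contact head
#' relies on) per directed fusion arrow — six arrows in total: alpha->beta,
#' beta->alpha, then peptide<->fused TCR in both directions for both chains —
#' plus the trainable temperature of the similarity map, reparameterized as
#' `tau = softplus(tau_raw)` so it stays positive.
#'
#' @param d Embedding dimension.
#' @param N Padded maximum sequence length (also the sigmoid slope of the
#'   contact filters and the normalizer `N^2` of the contact score).
#' @param bank A [threshold_bank()].
#' @param dropout Dropout rate applied to attention outputs during training.
#' @param tied If `TRUE`, the alpha- and beta-side arrows of each fusion
#'   stage share parameters (exact chain-swap symmetry); untied by default.
#' @param tau Initial temperature.
#' @param score_norm `"n2"` (default) divides the summed contact area by the
#'   padded maximum `N^2` exactly as the score definition states; `"valid"`
#'   divides by `L1 * L2`, the number of valid residue pairs, removing the
#'   sequence-length confound from the score.
#' @return Object of class `eml_params`.
#' @export
init_eml_params <- function(d, N, bank = threshold_bank(), dropout = 0.2,
                            tied = FALSE, tau = 1.0,
                            score_norm = c("n2", "valid")) {
  score_norm <- match.arg(score_norm)
  arrows <- stats::setNames(lapply(ARROW_NAMES, function(nm) .new_arrow(d)),
                            ARROW_NAMES)
  if (tied) {
    for (pr in TIED_PAIRS) arrows[[pr[2]]] <- arrows[[pr[1]]]
  }
  structure(list(arrows = arrows, tau_raw = inv_softplus(tau),
                 d = d, N = N, bank = bank, dropout = dropout, tied = tied,
                 score_norm = score_norm),
            class = "eml_params")
}

#' @export
print.eml_params <- function(x, ...) {
  np <- length(unlist(x$arrows)) + 1
  cat("<eml_params> d=", x$d, " N=", x$N, " |T|=",
      length(x$bank$thresholds), " tau=", signif(softplus(x$tau_raw), 4),
      " params=", np, if (x$tied) " (tied)" else "", "\n", sep = "")
  invisible(x)
}

#' Current temperature of the similarity map
#' @param params An `eml_params` object.
#' @export
eml_tau <- function(params) softplus(params$tau_raw)

#' Single-head cross-attention between two embedding blocks
#'
#' Computes `A(Q = query, K = V = keyvalue)`: scaled dot-product attention
#' with learned projections, followed by a residual connection. Attention
#' weights over key positions sum to 1 restricted to valid key positions;
#' padded key positions receive zero weight and padded query rows are zero
#' in the output.
#'
#' @param query,keyvalue `embedding_block`s of equal dimension `d`.
#' @param arrow Parameter list for one arrow (fields `Wq`, `Wk`, `Wv`),
#'   e.g. `params$arrows$ab`.
#' @return An `embedding_block` carrying the query's mask, with the `N x N`
#'   attention-weight matrix in attribute `"weights"`.
#' @export
cross_attend <- function(query, keyvalue, arrow) {
  if (ncol(query$matrix) != ncol(keyvalue$matrix))
    stop("embedding dimension mismatch: ", ncol(query$matrix), " vs ",
         ncol(keyvalue$matrix))
  N <- nrow(query$matrix)
  Lq <- query$valid_length; Lk <- keyvalue$valid_length
  fw <- .attn_forward(query$matrix[seq_len(Lq), , drop = FALSE], Lq,
                      keyvalue$matrix[seq_len(Lk), , drop = FALSE], Lk,
                      arrow, dropout = 0, train = FALSE)
  H <- matrix(0, N, ncol(query$matrix)); H[seq_len(Lq), ] <- fw$H
  P <- matrix(0, N, nrow(keyvalue$matrix)); P[seq_len(Lq), seq_len(Lk)] <- fw$cache$P
  out <- embedding_block(fw$H, query$sequence, N)
  attr(out, "weights") <- P
  out
}

#' Feature enhancement and fusion of the three chains
#'
#' Runs the six directed cross-attentions: first the alpha<->beta fusion
#' producing `e_ab` (CDR3a enriched by CDR3b) and `e_ba`, then the peptide is
#' fused with each in both directions, producing `e_e_ab`/`e_ab_e` (peptide
#' rows / CDR3a rows) and `e_e_ba`/`e_ba_e` (peptide rows / CDR3b rows).
#'
#' @param ea,eb,ee `embedding_block`s of the CDR3 alpha, CDR3 beta and
#'   peptide sequences.
#' @param params An `eml_params` object.
#' @return Object of class `fused_embeddings`: a list of the six blocks.
#' @export
fuse <- function(ea, eb, ee, params) {
  ar <- params$arrows
  e_ab <- cross_attend(ea, eb, ar$ab)
  e_ba <- cross_attend(eb, ea, ar$ba)
  structure(list(
    e_ab = e_ab, e_ba = e_ba,
    e_e_ab = cross_attend(ee, e_ab, ar$eab),
    e_ab_e = cross_attend(e_ab, ee, ar$abe),
    e_e_ba = cross_attend(ee, e_ba, ar$eba),
    e_ba_e = cross_attend(e_ba, ee, ar$bae)
  ), class = "fused_embeddings")
}

#' Pairwise similarity map of two embedding blocks
#'
#' `S[k, j]` is the cosine similarity of row `k` of `e1` and row `j` of
#' `e2`, clamped to \[0,1\] and divided by `max(tau, 1)` so the map stays in
#' \[0,1\] for any temperature. Rows/columns at padded positions are zero,
#' and zero-norm valid rows are treated as similarity 0.
#'
#' @param e1,e2 `embedding_block`s (or plain matrices, in which case all rows
#'   are treated as valid).
#' @param tau Positive temperature.
#' @return `N x N` numeric matrix.
#' @export
similarity_map <- function(e1, e2, tau = 1) {
  stopifnot(tau > 0)
  m1 <- if (inherits(e1, "embedding_block")) e1$matrix else as.matrix(e1)
  m2 <- if (inherits(e2, "embedding_block")) e2$matrix else as.matrix(e2)
  L1 <- if (inherits(e1, "embedding_block")) e1$valid_length else nrow(m1)
  L2 <- if (inherits(e2, "embedding_block")) e2$valid_length else nrow(m2)
  S <- matrix(0, nrow(m1), nrow(m2))
  cs <- .cosine_clamped(m1[seq_len(L1), , drop = FALSE],
                        m2[seq_len(L2), , drop = FALSE])
  S[seq_len(L1), seq_len(L2)] <- cs$C / max(tau, 1)
  S
}

# clamped cosine of all row pairs; zero-norm rows give 0
.cosine_clamped <- function(U, V) {
  nu <- sqrt(rowSums(U * U)); nv <- sqrt(rowSums(V * V))
  dn <- outer(nu, nv)
  zero <- dn == 0
  dn[zero] <- 1
  Craw <- (U %*% t(V)) / dn
  Craw[zero] <- 0
  list(Craw = Craw, C = pmin(pmax(Craw, 0), 1), nu = nu, nv = nv,
       zero = zero)
}

#' Differentiable contact filter at one threshold
#'
#' Smooth approximation of the hard rule "residue pairs with similarity
#' above `t_i` are in contact": `M_i = sigmoid((S - t_i) * N)`. The slope
#' `N` (the padded maximum length) makes the filter sharp while keeping it
#' differentiable; `M_i = 0.5` exactly where `S = t_i`.
#'
#' @param S Similarity matrix.
#' @param t_i Threshold in \[0,1\].
#' @param N Sigmoid slope.
#' @return Matrix of the same shape with entries in (0,1).
#' @export
contact_filter <- function(S, t_i, N) sigmoid((S - t_i) * N)

#' Aggregate filtered maps into a contact-area map
#'
#' `A' = (1/|T|) * sum_i A_i * M_i`, where `A_i` is the i-th softmax area
#' weight of the threshold bank (a scalar scaling the whole filtered map).
#'
#' @param filters List of `|T|` filtered maps `M_i`.
#' @param bank The [threshold_bank()] that produced them.
#' @return Contact-area matrix with entries in \[0,1\].
#' @export
aggregate_area <- function(filters, bank) {
  a <- bank$area_weights
  if (length(filters) != length(a))
    stop("number of filters (", length(filters),
         ") != number of thresholds (", length(a), ")")
  Reduce(`+`, Map(function(w, M) w * M, a, filters)) / length(a)
}

#' Scalar contact score of an area map
#'
#' The mean contact area `w = (1/N^2) * sum_{k,j} A'[k,j]`, where `N^2` is
#' the maximum possible contact area of the padded map.
#'
#' @param area `N x N` contact-area matrix.
#' @param N Padded maximum length (defaults to `nrow(area)`).
#' @return Scalar in \[0,1\].
#' @export
contact_score <- function(area, N = nrow(area)) sum(area) / N^2

#' Contact prototype function
#'
#' The full differentiable pipeline `f(E1, E2) -> [0,1]`: cosine similarity
#' map (clamped, temperature-scaled), `|T|` sigmoid contact filters,
#' area-weighted aggregation, and the scalar contact score. All
#' intermediates are returned so the map itself serves as the explanation.
#' Padded rows/columns of the area map are zero.
#'
#' @param e1,e2 `embedding_block`s (conventionally: peptide rows, TCR-chain
#'   rows).
#' @param params An `eml_params` object (supplies `tau`, the threshold bank
#'   and `N`).
#' @return Object of class `contact_map` with fields `similarity`, `filters`
#'   (list of `M_i`), `area` (`A'`), `score` (`w`), `l1`, `l2`.
#' @export
contact_prototype <- function(e1, e2, params) {
  N <- nrow(e1$matrix)
  pf <- .proto_forward(e1$matrix[seq_len(e1$valid_length), , drop = FALSE],
                       e2$matrix[seq_len(e2$valid_length), , drop = FALSE],
                       eml_tau(params), params$bank, N, .norm_is_n2(params))
  pad <- function(m) {
    out <- matrix(0, N, N)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  structure(list(similarity = pad(pf$S),
                 filters = lapply(pf$Ms, pad),
                 area = pad(pf$A),
                 score = pf$w,
                 l1 = e1$valid_length, l2 = e2$valid_length),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$l1, " x ", x$l2, " valid of ",
      nrow(x$area), " x ", ncol(x$area), ", score w = ",
      signif(x$score, 4), "\n", sep = "")
  invisible(x)
}

#' Predict binding from fused embeddings
#'
#' Applies the contact prototype to both chains: `map_a` pairs the
#' peptide-row block fused through the alpha chain with the CDR3a-row block
#' (`f(e_e_ab, e_ab_e)`), `map_b` likewise for CDR3b, and the binding score
#' is the mean of the two chain contact scores,
#' `y_hat = (w_a + w_b) / 2`.
#'
#' @param fused A `fused_embeddings` object from [fuse()].
#' @param params An `eml_params` object.
#' @return List with `y_hat` (scalar in \[0,1\]), `map_a` and `map_b`
#'   (`contact_map`s with peptide rows and TCR-chain columns).
#' @export
eml_predict <- function(fused, params) {
  map_a <- contact_prototype(fused$e_e_ab, fused$e_ab_e, params)
  map_b <- contact_prototype(fused$e_e_ba, fused$e_ba_e, params)
  list(y_hat = (map_a$score + map_b$score) / 2, map_a = map_a, map_b = map_b)
}

#' Class-weighted binary cross-entropy loss
#'
#' `L = -[w_pos * y * log(y_hat) + (1 - y) * log(1 - y_hat)]`, with `y_hat`
#' clamped to `[1e-7, 1 - 1e-7]`; vectors are reduced by the mean. The
#' positive-class weight compensates the negative:positive imbalance of the
#' training data (weight 4 for the canonical 4:1 ratio).
#'
#' @param y_hat Predicted probabilities in \[0,1\].
#' @param y Binary labels.
#' @param pos_weight Positive-class weight (> 0).
#' @return Scalar mean loss.
#' @export
eml_loss <- function(y_hat, y, pos_weight = 1) {
  stopifnot(pos_weight > 0, length(y_hat) == length(y))
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  mean(-(pos_weight * y * log(p) + (1 - y) * log(1 - p)))
}
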