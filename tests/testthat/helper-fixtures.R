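# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain scalar loops, independent of the vectorized implementation paths
# they check.

rand_seq <- function(n) paste(sample(tcrcontact:::AA20, n, replace = TRUE),
                              collapse = "")

# random embedding block with L valid rows out of N
rand_block <- function(L, d, N, sd = 1) {
  embedding_block(matrix(rnorm(L * d, sd = sd), L, d), rand_seq(L), N)
}

tiny_world <- function(seed = 7, ...) {
  generate_world(n_contacts = 3L, pep_len_range = c(5L, 7L),
                 cdr_len_range = c(6L, 9L), d = 10L, max_len = 12L,
                 codebook_rank = 6L, seed = seed, ...)
}

small_triads <- function() {
  data.frame(
    cdr3a = c("CASSA", "CASSC", "CAWD", "CAVE"),
    cdr3b = c("CSARD", "CSARE", "CSGF", "CSGH"),
    peptide = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV"),
    label = 1L,
    epitope_id = c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV"),
    source = "test", mhc_class = "I", provenance = "positive",
    stringsAsFactors = FALSE)
}

# scalar-loop contact prototype: Eqs similarity -> filters -> area -> score,
# computed cell by cell over valid rows only, padded cells fixed at zero.
proto_oracle <- function(E1, E2, tau, thresholds, N) {
  L1 <- nrow(E1); L2 <- nrow(E2)
  nT <- length(thresholds)
  # softmax by loop
  ex <- numeric(nT)
  for (i in seq_len(nT)) ex[i] <- exp(thresholds[i] - max(thresholds))
  aw <- ex / sum(ex)
  S <- matrix(0, N, N)
  A <- matrix(0, N, N)
  Ms <- lapply(seq_len(nT), function(i) matrix(0, N, N))
  for (k in seq_len(L1)) {
    for (j in seq_len(L2)) {
      num <- 0; n1 <- 0; n2 <- 0
      for (t in seq_len(ncol(E1))) {
        num <- num + E1[k, t] * E2[j, t]
        n1 <- n1 + E1[k, t]^2
        n2 <- n2 + E2[j, t]^2
      }
      cth <- if (n1 == 0 || n2 == 0) 0 else num / sqrt(n1 * n2)
      cth <- min(max(cth, 0), 1)
      S[k, j] <- cth / max(tau, 1)
      for (i in seq_len(nT)) {
        m <- 1 / (1 + exp(-(S[k, j] - thresholds[i]) * N))
        Ms[[i]][k, j] <- m
        A[k, j] <- A[k, j] + aw[i] * m / nT
      }
    }
  }
  w <- 0
  for (k in seq_len(N)) for (j in seq_len(N)) w <- w + A[k, j]
  list(S = S, Ms = Ms, A = A, w = w / N^2)
}

# full single-head attention block by scalar loops (projection, softmax,
# weighted value sum, residual connection)
attn_oracle <- function(Xq, Xkv, W) {
  d <- ncol(Xq)
  Q <- Xq %*% W$Wq; K <- Xkv %*% W$Wk; V <- Xkv %*% W$Wv
  H <- matrix(0, nrow(Xq), d)
  P <- matrix(0, nrow(Xq), nrow(Xkv))
  for (i in seq_len(nrow(Xq))) {
    sc <- numeric(nrow(Xkv))
    for (j in seq_len(nrow(Xkv)))
      sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(sc - max(sc)); p <- e / sum(e)
    P[i, ] <- p
    o <- numeric(d)
    for (j in seq_len(nrow(Xkv))) o <- o + p[j] * V[j, ]
    H[i, ] <- Xq[i, ] + o
  }
  list(H = H, P = P)
}

# full ROC-AUC by the Mann-Whitney pair statistic (ties count 1/2)
auc_pairs_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# mean BRHR of a prediction over the four chain directions of one record
record_brhr <- function(map_a, map_b, dmap, t = 0.25) {
  dv <- distance_vectors(dmap)
  mean(c(
    brhr(residue_importance(map_a, "peptide"), dv$pep_to_cdr3a, t)$hit_rate,
    brhr(residue_importance(map_b, "peptide"), dv$pep_to_cdr3b, t)$hit_rate,
    brhr(residue_importance(map_a, "tcr"), dv$cdr3a_to_pep, t)$hit_rate,
    brhr(residue_importance(map_b, "tcr"), dv$cdr3b_to_pep, t)$hit_rate))
}

# synthetic train/test bundle used by training and acceptance tests
make_synth_setup <- function(world, n_pos_train, n_pos_test = NULL,
                             neg_ratio = 4, seed_train = 101, seed_test = 202) {
  tr <- generate_dataset(world, n_pos = n_pos_train, neg_ratio = neg_ratio,
                         seed = seed_train)
  te <- if (!is.null(n_pos_test))
    generate_dataset(world, n_pos = n_pos_test, neg_ratio = neg_ratio,
                     seed = seed_test) else NULL
  seqs <- c(tr$records$cdr3a, tr$records$cdr3b, tr$records$peptide)
  if (!is.null(te)) seqs <- c(seqs, te$records$cdr3a, te$records$cdr3b,
                              te$records$peptide)
  store <- build_store(unique(seqs), synthetic_provider(world))
  list(train = tr, test = te, store = store)
}
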