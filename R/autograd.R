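# Internal forward/backward kernels for training.
#
# All kernels operate on cropped matrices (padding rows removed); padding is
# reinstated only when explanation maps are returned to the user. Gradients
# are analytic; tests check them against central finite differences.

# ---- attention -------------------------------------------------------------

# Xq: Lq x d, Xkv: Lk x d (cropped to valid rows). Returns H (Lq x d) and a
# cache sufficient for the backward pass.
.attn_forward <- function(Xq, Lq, Xkv, Lk, W, dropout = 0, train = FALSE) {
  d <- ncol(Xq)
  Q <- Xq %*% W$Wq
  K <- Xkv %*% W$Wk
  V <- Xkv %*% W$Wv
  Scr <- Q %*% t(K) / sqrt(d)
  E <- exp(Scr - apply(Scr, 1, max))
  P <- E / rowSums(E)
  O <- P %*% V
  dm <- NULL
  if (train && dropout > 0) {
    dm <- matrix(stats::rbinom(length(O), 1L, 1 - dropout), nrow(O), ncol(O))
    O <- O * dm / (1 - dropout)
  }
  H <- Xq + O
  list(H = H,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, P = P,
                    dm = dm, dropout = dropout, d = d))
}

# dH: gradient wrt H (Lq x d). Returns gradients wrt both inputs and the
# arrow's parameters.
.attn_backward <- function(dH, cache, W) {
  d <- cache$d
  dO <- dH
  if (!is.null(cache$dm)) dO <- dO * cache$dm / (1 - cache$dropout)
  dP <- dO %*% t(cache$V)
  dV <- t(cache$P) %*% dO
  dScr <- cache$P * (dP - rowSums(dP * cache$P))
  dQ <- dScr %*% cache$K / sqrt(d)
  dK <- t(dScr) %*% cache$Q / sqrt(d)
  list(dXq = dH + dQ %*% t(W$Wq),
       dXkv = dK %*% t(W$Wk) + dV %*% t(W$Wv),
       grads = list(Wq = t(cache$Xq) %*% dQ,
                    Wk = t(cache$Xkv) %*% dK,
                    Wv = t(cache$Xkv) %*% dV))
}

# ---- contact prototype -----------------------------------------------------

# E1: L1 x d, E2: L2 x d (cropped). N is the padded maximum length used both
# as sigmoid slope and as the score normalizer N^2.
.proto_forward <- function(E1, E2, tau, bank, N, norm_n2 = TRUE) {
  cs <- .cosine_clamped(E1, E2)
  D <- max(tau, 1)
  S <- cs$C / D
  Ms <- lapply(bank$thresholds, function(t_i) sigmoid((S - t_i) * N))
  A <- Reduce(`+`, Map(function(w, M) w * M, bank$area_weights, Ms)) /
    length(Ms)
  denom <- if (norm_n2) N^2 else nrow(E1) * nrow(E2)
  w <- sum(A) / denom
  list(S = S, Ms = Ms, A = A, w = w,
       cache = list(E1 = E1, E2 = E2, cs = cs, D = D, tau = tau,
                    bank = bank, N = N, denom = denom))
}

.proto_backward <- function(dw, fw, tau_raw) {
  ca <- fw$cache
  N <- ca$N; bank <- ca$bank; cs <- ca$cs
  dA <- dw / ca$denom
  sig_term <- Reduce(`+`, Map(function(wgt, M) wgt * M * (1 - M),
                              bank$area_weights, fw$Ms))
  dS <- dA * (N / length(fw$Ms)) * sig_term
  # temperature path: S = C / D, D = max(tau, 1)
  dD <- -sum(dS * cs$C) / ca$D^2
  dtau_raw <- dD * as.numeric(ca$tau > 1) * sigmoid(tau_raw)
  # clamp: gradient flows only where the raw cosine is in (0, 1)
  G <- dS / ca$D
  G[!(cs$Craw > 0 & cs$Craw < 1)] <- 0
  G[cs$zero] <- 0
  nu <- ifelse(cs$nu == 0, 1, cs$nu)
  nv <- ifelse(cs$nv == 0, 1, cs$nv)
  Gn <- G / outer(nu, nv)
  dE1 <- Gn %*% ca$E2 - (rowSums(G * cs$Craw) / nu^2) * ca$E1
  dE2 <- t(Gn) %*% ca$E1 - (colSums(G * cs$Craw) / nv^2) * ca$E2
  list(dE1 = dE1, dE2 = dE2, dtau_raw = dtau_raw)
}

# ---- whole record ----------------------------------------------------------

# ea/eb/ee: cropped valid-row matrices for one record.
.record_forward <- function(ea, eb, ee, params, train = FALSE) {
  ar <- params$arrows
  p <- if (train) params$dropout else 0
  La <- nrow(ea); Lb <- nrow(eb); Le <- nrow(ee)
  ab <- .attn_forward(ea, La, eb, Lb, ar$ab, p, train)
  ba <- .attn_forward(eb, Lb, ea, La, ar$ba, p, train)
  eab <- .attn_forward(ee, Le, ab$H, La, ar$eab, p, train)
  abe <- .attn_forward(ab$H, La, ee, Le, ar$abe, p, train)
  eba <- .attn_forward(ee, Le, ba$H, Lb, ar$eba, p, train)
  bae <- .attn_forward(ba$H, Lb, ee, Le, ar$bae, p, train)
  tau <- softplus(params$tau_raw)
  n2 <- .norm_is_n2(params)
  pa <- .proto_forward(eab$H, abe$H, tau, params$bank, params$N, n2)
  pb <- .proto_forward(eba$H, bae$H, tau, params$bank, params$N, n2)
  list(y_hat = (pa$w + pb$w) / 2, w_a = pa$w, w_b = pb$w,
       cache = list(ab = ab, ba = ba, eab = eab, abe = abe,
                    eba = eba, bae = bae, pa = pa, pb = pb))
}

# dy: dL/dy_hat for this record. Returns a grad list shaped like params
# (arrows + tau_raw).
.record_backward <- function(dy, fw, params) {
  ca <- fw$cache
  pa_b <- .proto_backward(dy / 2, ca$pa, params$tau_raw)
  pb_b <- .proto_backward(dy / 2, ca$pb, params$tau_raw)
  g <- list()
  bk_eab <- .attn_backward(pa_b$dE1, ca$eab$cache, params$arrows$eab)
  bk_abe <- .attn_backward(pa_b$dE2, ca$abe$cache, params$arrows$abe)
  bk_eba <- .attn_backward(pb_b$dE1, ca$eba$cache, params$arrows$eba)
  bk_bae <- .attn_backward(pb_b$dE2, ca$bae$cache, params$arrows$bae)
  d_ab <- bk_eab$dXkv + bk_abe$dXq
  d_ba <- bk_eba$dXkv + bk_bae$dXq
  bk_ab <- .attn_backward(d_ab, ca$ab$cache, params$arrows$ab)
  bk_ba <- .attn_backward(d_ba, ca$ba$cache, params$arrows$ba)
  list(arrows = list(ab = bk_ab$grads, ba = bk_ba$grads,
                     eab = bk_eab$grads, abe = bk_abe$grads,
                     eba = bk_eba$grads, bae = bk_bae$grads),
       tau_raw = pa_b$dtau_raw + pb_b$dtau_raw)
}

.zero_grads <- function(params) {
  zl <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
    numeric(length(x))
  list(arrows = lapply(params$arrows, function(a) lapply(a, zl)),
       tau_raw = 0)
}

.add_grads <- function(acc, g, scale = 1) {
  for (nm in names(acc$arrows))
    for (f in names(acc$arrows[[nm]]))
      acc$arrows[[nm]][[f]] <- acc$arrows[[nm]][[f]] + scale * g$arrows[[nm]][[f]]
  acc$tau_raw <- acc$tau_raw + scale * g$tau_raw
  acc
}

# average gradients across tied arrow pairs so shared parameters stay shared
.tie_grads <- function(g) {
  for (pr in TIED_PAIRS) {
    for (f in names(g$arrows[[pr[1]]])) {
      m <- (g$arrows[[pr[1]]][[f]] + g$arrows[[pr[2]]][[f]]) / 2
      g$arrows[[pr[1]]][[f]] <- m
      g$arrows[[pr[2]]][[f]] <- m
    }
  }
  g
}

# ---- flatten / restore -----------------------------------------------------

.flatten_params <- function(params) {
  c(unlist(params$arrows, use.names = TRUE), tau_raw = params$tau_raw)
}

.unflatten_params <- function(flat, skeleton) {
  n <- length(flat)
  rel <- utils::relist(flat[-n], skeleton$arrows)
  # relist drops matrix dims; restore them
  for (nm in names(rel))
    for (f in names(rel[[nm]]))
      if (is.matrix(skeleton$arrows[[nm]][[f]]))
        dim(rel[[nm]][[f]]) <- dim(skeleton$arrows[[nm]][[f]])
  out <- skeleton
  out$arrows <- rel
  out$tau_raw <- unname(flat[n])
  out
}

.flatten_grads <- function(g) {
  c(unlist(g$arrows, use.names = FALSE), g$tau_raw)
}

# logical vector: which flat entries receive weight decay (projections only,
# not the temperature)
.decay_mask <- function(params) {
  n <- length(unlist(params$arrows, use.names = FALSE))
  c(rep(TRUE, n), FALSE)
}

.norm_is_n2 <- function(params) is.null(params$score_norm) ||
  identical(params$score_norm, "n2")
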