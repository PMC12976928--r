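test_that("threshold bank is ordered, in range, with softmax area weights", {
  bk <- threshold_bank(10)
  expect_length(bk$thresholds, 10)
  expect_equal(bk$thresholds, (1:10) / 11)
  expect_equal(sum(bk$area_weights), 1)
  expect_true(all(diff(bk$area_weights) > 0)) # larger thresholds weigh more
  expect_error(threshold_bank(thresholds = c(0.5, 0.2)), "increasing")
  expect_error(threshold_bank(thresholds = c(0.5, 1.2)), "0,1")
})

test_that("cross-attention puts weight 1 on a single valid key and zeros padding", {
  set.seed(1)
  d <- 4
  params <- init_eml_params(d, 6, bank = threshold_bank(3))
  q <- rand_block(3, d, 6)
  kv <- rand_block(1, d, 6) # single valid key position
  out <- cross_attend(q, kv, params$arrows$ab)
  W <- attr(out, "weights")
  expect_equal(W[1:3, 1], rep(1, 3)) # softmax over one element
  expect_true(all(W[, 2:6] == 0))
  expect_true(all(out$matrix[4:6, ] == 0)) # padded query rows zero
  expect_error(cross_attend(q, rand_block(2, 5, 6), params$arrows$ab),
               "dimension mismatch")
})

test_that("an all-zero query yields uniform attention over valid keys", {
  set.seed(2)
  params <- init_eml_params(4, 6, bank = threshold_bank(3))
  q <- embedding_block(matrix(0, 2, 4), "CA", 6)
  kv <- rand_block(4, 4, 6)
  W <- attr(cross_attend(q, kv, params$arrows$ab), "weights")
  expect_equal(W[1, 1:4], rep(0.25, 4))
  expect_true(all(is.finite(W)))
})

test_that("cross-attention matches a scalar-loop single-head oracle", {
  set.seed(3)
  d <- 4
  params <- init_eml_params(d, 5, bank = threshold_bank(3))
  W <- params$arrows$ab
  q <- rand_block(3, d, 5)
  kv <- rand_block(4, d, 5)
  oc <- attn_oracle(q$matrix[1:3, ], kv$matrix[1:4, ], W)
  out <- cross_attend(q, kv, W)
  expect_equal(out$matrix[1:3, ], oc$H, tolerance = 1e-12)
  expect_equal(attr(out, "weights")[1:3, 1:4], oc$P, tolerance = 1e-12)
})

test_that("fusion is chain-swap symmetric when parameters are tied", {
  set.seed(4)
  d <- 6
  params <- init_eml_params(d, 8, bank = threshold_bank(4), tied = TRUE)
  ea <- rand_block(5, d, 8); eb <- rand_block(7, d, 8); ee <- rand_block(4, d, 8)
  f1 <- fuse(ea, eb, ee, params)
  f2 <- fuse(eb, ea, ee, params) # swap the two TCR chains
  expect_equal(f2$e_ab$matrix, f1$e_ba$matrix)
  expect_equal(f2$e_ba$matrix, f1$e_ab$matrix)
  expect_equal(f2$e_e_ab$matrix, f1$e_e_ba$matrix)
  expect_equal(f2$e_ab_e$matrix, f1$e_ba_e$matrix)
  # untied by default: symmetry broken
  pu <- init_eml_params(d, 8, bank = threshold_bank(4))
  g1 <- fuse(ea, eb, ee, pu); g2 <- fuse(eb, ea, ee, pu)
  expect_gt(max(abs(g2$e_ab$matrix - g1$e_ba$matrix)), 1e-6)
})

test_that("padded rows of any input never influence fusion outputs", {
  set.seed(5)
  d <- 6
  params <- init_eml_params(d, 8, bank = threshold_bank(4))
  ea <- rand_block(5, d, 8); eb <- rand_block(7, d, 8); ee <- rand_block(4, d, 8)
  base <- fuse(ea, eb, ee, params)
  ee2 <- ee
  ee2$matrix[5:8, ] <- matrix(rnorm(4 * d, sd = 10), 4, d) # corrupt padding
  pert <- fuse(ea, eb, ee2, params)
  for (nm in names(base))
    expect_identical(base[[nm]]$matrix, pert[[nm]]$matrix)
})

test_that("similarity map obeys the cosine/clamp/temperature rules", {
  set.seed(6)
  b <- rand_block(4, 5, 6)
  S <- similarity_map(b, b, tau = 1)
  expect_equal(diag(S)[1:4], rep(1, 4)) # cosine of a vector with itself
  expect_true(all(S[5:6, ] == 0) && all(S[, 5:6] == 0))
  u <- embedding_block(rbind(c(1, 0), c(0, 1), c(-1, 0)), "CAS", 4)
  S2 <- similarity_map(u, u, tau = 1)
  expect_equal(S2[1, 2], 0)      # orthogonal rows
  expect_equal(S2[1, 3], 0)      # anti-parallel rows clamp to 0
  # zero-norm valid row is similarity 0, not an error
  z <- embedding_block(rbind(c(0, 0), c(1, 1)), "CA", 4)
  expect_equal(similarity_map(z, u, tau = 1)[1, ], rep(0, 4))
  # temperature divides, with effective divisor max(tau, 1)
  expect_equal(similarity_map(b, b, tau = 2), S / 2)
  expect_equal(similarity_map(b, b, tau = 0.5), S)
  expect_error(similarity_map(b, b, tau = 0), "tau > 0")
})

test_that("contact filter is a sharp sigmoid with the documented fixed points", {
  expect_equal(contact_filter(matrix(0.3), 0.3, 25)[1, 1], 0.5)
  expect_equal(contact_filter(matrix(1), 0, 25)[1, 1], 1, tolerance = 1e-10)
  set.seed(7)
  S <- matrix(runif(16), 4, 4)
  M <- contact_filter(S, 0.5, 4)
  for (k in 1:4) for (j in 1:4)
    expect_equal(M[k, j], 1 / (1 + exp(-(S[k, j] - 0.5) * 4)))
  expect_true(all(M > 0 & M < 1))
})

test_that("area aggregation weights filters by the softmax of thresholds", {
  bk1 <- threshold_bank(thresholds = 0.4)
  M <- matrix(runif(9), 3, 3)
  expect_equal(aggregate_area(list(M), bk1), M) # singleton softmax is 1
  bk3 <- threshold_bank(3)
  expect_equal(aggregate_area(list(M, M, M), bk3), M / 3) # weights sum to 1
  set.seed(8)
  Ms <- lapply(1:3, function(i) matrix(runif(9), 3, 3))
  A <- aggregate_area(Ms, bk3)
  # scalar triple-loop oracle
  ref <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) for (j in 1:3)
    ref[k, j] <- ref[k, j] + bk3$area_weights[i] * Ms[[i]][k, j] / 3
  expect_equal(A, ref, tolerance = 1e-14)
  expect_error(aggregate_area(Ms[1:2], bk3), "thresholds")
})

test_that("contact score is the mean area over the padded frame", {
  expect_equal(contact_score(matrix(1, 4, 4)), 1)
  expect_equal(contact_score(matrix(0, 4, 4)), 0)
  A <- matrix(0, 5, 5); A[2, 3] <- 0.5
  expect_equal(contact_score(A, 5), 0.02)
})

test_that("the full prototype pipeline matches the scalar-loop oracle", {
  set.seed(9)
  params <- init_eml_params(8, 6, bank = threshold_bank(10), tau = 1.3)
  for (rep in 1:10) {
    e1 <- rand_block(sample(3:6, 1), 8, 6)
    e2 <- rand_block(sample(3:6, 1), 8, 6)
    cm <- contact_prototype(e1, e2, params)
    oc <- proto_oracle(e1$matrix[seq_len(e1$valid_length), , drop = FALSE],
                       e2$matrix[seq_len(e2$valid_length), , drop = FALSE],
                       eml_tau(params), params$bank$thresholds, 6)
    expect_lt(max(abs(cm$area - oc$A)), 1e-12)
    expect_equal(cm$score, oc$w, tolerance = 1e-12)
  }
})

test_that("raising similarity never decreases the contact score", {
  set.seed(10)
  bk <- threshold_bank(5)
  S <- matrix(runif(25), 5, 5)
  w0 <- contact_score(aggregate_area(
    lapply(bk$thresholds, contact_filter, S = S, N = 5), bk))
  for (trial in 1:20) {
    S2 <- S
    ij <- sample(25, 1)
    S2[ij] <- min(1, S2[ij] + runif(1, 0, 0.5))
    w1 <- contact_score(aggregate_area(
      lapply(bk$thresholds, contact_filter, S = S2, N = 5), bk))
    expect_gte(w1, w0)
  }
})

test_that("binding score is the mean of the two chain contact scores", {
  set.seed(11)
  params <- init_eml_params(6, 8, bank = threshold_bank(4))
  ea <- rand_block(5, 6, 8); eb <- rand_block(6, 6, 8); ee <- rand_block(4, 6, 8)
  pr <- eml_predict(fuse(ea, eb, ee, params), params)
  expect_equal(pr$y_hat, (pr$map_a$score + pr$map_b$score) / 2)
  expect_true(pr$y_hat >= 0 && pr$y_hat <= 1)
  # map_a pairs peptide rows with CDR3a columns, map_b with CDR3b
  expect_equal(c(pr$map_a$l1, pr$map_a$l2), c(4, 5))
  expect_equal(c(pr$map_b$l1, pr$map_b$l2), c(4, 6))
})

test_that("the class-weighted loss reproduces its closed forms", {
  expect_equal(eml_loss(0.5, 1, 1), log(2), tolerance = 1e-9)
  expect_equal(eml_loss(0.5, 1, 4), 4 * log(2), tolerance = 1e-9)
  expect_equal(eml_loss(c(0, 1), c(0, 1)), -log(1 - 1e-7), tolerance = 1e-9)
  set.seed(12)
  yh <- runif(20); y <- rbinom(20, 1, 0.5); pw <- 3.5
  ref <- 0
  for (i in 1:20) {
    p <- min(max(yh[i], 1e-7), 1 - 1e-7)
    ref <- ref - (pw * y[i] * log(p) + (1 - y[i]) * log(1 - p))
  }
  expect_equal(eml_loss(yh, y, pw), ref / 20, tolerance = 1e-12)
  expect_error(eml_loss(0.5, 1, 0), "pos_weight")
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  d <- 6
  params <- init_eml_params(d, 10, bank = threshold_bank(4), tau = 1.5)
  params$dropout <- 0
  blocks <- lapply(1:3, function(i) list(
    ea = matrix(rnorm(7 * d), 7, d), eb = matrix(rnorm(8 * d), 8, d),
    ee = matrix(rnorm(5 * d), 5, d)))
  y <- c(1, 0, 1); pw <- 2
  lossfun <- function(p) {
    yh <- vapply(blocks, function(bl)
      tcrcontact:::.record_forward(bl$ea, bl$eb, bl$ee, p)$y_hat, numeric(1))
    eml_loss(yh, y, pw)
  }
  acc <- tcrcontact:::.zero_grads(params)
  for (i in 1:3) {
    fw <- tcrcontact:::.record_forward(blocks[[i]]$ea, blocks[[i]]$eb,
                                       blocks[[i]]$ee, params)
    dy <- (-pw * y[i] / fw$y_hat + (1 - y[i]) / (1 - fw$y_hat)) / 3
    acc <- tcrcontact:::.add_grads(acc, tcrcontact:::.record_backward(dy, fw, params))
  }
  ga <- tcrcontact:::.flatten_grads(acc)
  flat <- tcrcontact:::.flatten_params(params)
  idx <- c(sample(length(flat) - 1, 30), length(flat)) # incl. tau_raw
  h <- 1e-5
  for (j in idx) {
    f1 <- flat; f1[j] <- f1[j] + h
    f2 <- flat; f2[j] <- f2[j] - h
    fd <- (lossfun(tcrcontact:::.unflatten_params(f1, params)) -
             lossfun(tcrcontact:::.unflatten_params(f2, params))) / (2 * h)
    denom <- max(abs(fd), 1e-6)
    expect_lt(abs(ga[j] - fd) / denom, 1e-4)
  }
})
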