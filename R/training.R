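# Deterministic training loop (AdamW, gradient clipping, dropout,
# class-weighted loss) and batch inference.

#' Training configuration
#'
#' Defaults follow the reference regimen: AdamW, learning rate 1e-3, batch
#' size 512, dropout 0.2, 150 epochs, positive-class weight set automatically
#' to the negative:positive ratio of the training set. For checkpoint
#' selection, a fraction of training epitopes is held out as a validation
#' set and the parameters with the lowest validation loss are retained
#' (`val_fraction = 0` keeps the last epoch instead).
#'
#' @param epochs Number of epochs.
#' @param batch_size Records per gradient step.
#' @param learning_rate AdamW step size.
#' @param weight_decay AdamW decoupled weight decay (projection matrices
#'   only).
#' @param dropout Dropout rate on attention outputs.
#' @param seed Integer seed controlling initialization, shuffling, the
#'   validation split and dropout; a fixed seed makes training bit-for-bit
#'   reproducible.
#' @param pos_weight `"auto"` (negatives/positives) or an explicit positive
#'   real.
#' @param val_fraction Fraction of training epitopes held out for checkpoint
#'   selection.
#' @param clip_norm Global gradient-norm clip; the sharp sigmoid contact
#'   filters (slope `N`) can produce steep gradients.
#' @param n_thresholds Size of the contact [threshold_bank()].
#' @param tied Tie the alpha/beta-side attention parameters (chain-swap
#'   symmetric model).
#' @param adam_beta1,adam_beta2,adam_eps AdamW moment constants.
#' @param engine `"cpp"` (compiled kernels, default) or `"r"` (reference
#'   implementation); both compute the same forward pass and analytic
#'   gradients.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 150L, batch_size = 512L,
                         learning_rate = 1e-3, weight_decay = 1e-2,
                         dropout = 0.2, seed = 1L, pos_weight = "auto",
                         val_fraction = 0.1, clip_norm = 1.0,
                         n_thresholds = 10L, tied = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, engine = c("cpp", "r"),
                         score_norm = c("n2", "valid")) {
  engine <- match.arg(engine)
  score_norm <- match.arg(score_norm)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, dropout >= 0,
            dropout < 1, val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, seed = as.integer(seed),
                 pos_weight = pos_weight, val_fraction = val_fraction,
                 clip_norm = clip_norm, n_thresholds = as.integer(n_thresholds),
                 tied = tied, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 engine = engine, score_norm = score_norm),
            class = "train_config")
}

# cropped valid-row matrices for each record, fetched once
.crop_blocks <- function(records, store) {
  lapply(seq_len(nrow(records)), function(i) {
    ga <- store_lookup(store, records$cdr3a[i])
    gb <- store_lookup(store, records$cdr3b[i])
    ge <- store_lookup(store, records$peptide[i])
    list(ea = ga$matrix[seq_len(ga$valid_length), , drop = FALSE],
         eb = gb$matrix[seq_len(gb$valid_length), , drop = FALSE],
         ee = ge$matrix[seq_len(ge$valid_length), , drop = FALSE])
  })
}

.forward_scores <- function(blocks, params, engine = "cpp") {
  if (engine == "cpp") {
    res <- cpp_batch(blocks, numeric(0), 1, .flatten_params(params),
                     params$d, params$N, params$bank$thresholds,
                     params$bank$area_weights, 0, FALSE, FALSE,
                     .norm_is_n2(params))
    return(res$y_hat)
  }
  vapply(blocks, function(bl)
    .record_forward(bl$ea, bl$eb, bl$ee, params, train = FALSE)$y_hat,
    numeric(1))
}

# loss + flat gradient of one mini-batch, by either engine; the R engine is
# the reference implementation, the C++ engine the fast path
.batch_grad <- function(blocks, y, pw, params, flat, engine) {
  if (engine == "cpp") {
    res <- cpp_batch(blocks, as.numeric(y), pw, flat, params$d, params$N,
                     params$bank$thresholds, params$bank$area_weights,
                     params$dropout, TRUE, TRUE, .norm_is_n2(params))
    return(list(loss = res$loss, grad = res$grad))
  }
  B <- length(blocks)
  eps_c <- 1e-7
  acc <- .zero_grads(params)
  bloss <- 0
  for (i in seq_len(B)) {
    bl <- blocks[[i]]
    fw <- .record_forward(bl$ea, bl$eb, bl$ee, params, train = TRUE)
    p <- min(max(fw$y_hat, eps_c), 1 - eps_c)
    bloss <- bloss - (pw * y[i] * log(p) + (1 - y[i]) * log(1 - p))
    if (fw$y_hat > eps_c && fw$y_hat < 1 - eps_c) {
      dy <- (-pw * y[i] / p + (1 - y[i]) / (1 - p)) / B
      acc <- .add_grads(acc, .record_backward(dy, fw, params))
    }
  }
  list(loss = bloss / B, grad = .flatten_grads(acc))
}

# average tied arrow pairs on a flat gradient (layout of .flatten_params)
.tie_flat <- function(g, d) {
  s <- 3 * d * d
  for (pr in list(c(1, 2), c(3, 5), c(4, 6))) {
    i1 <- ((pr[1] - 1) * s + 1):(pr[1] * s)
    i2 <- ((pr[2] - 1) * s + 1):(pr[2] * s)
    m <- (g[i1] + g[i2]) / 2
    g[i1] <- m; g[i2] <- m
  }
  g
}

#' Train the explainable binding model
#'
#' Runs the full regimen: per-epoch shuffling, mini-batch analytic
#' gradients of the class-weighted cross-entropy, global-norm clipping, and
#' AdamW updates. Logging records train and validation loss per epoch; the
#' returned checkpoint holds the parameters with the lowest validation loss.
#' Training is bit-for-bit reproducible under a fixed `config$seed`.
#'
#' @param records Triad data frame with labels in `{0,1}`.
#' @param store An [build_store()] embedding store covering every sequence.
#' @param config A [train_config()].
#' @return Object of class `eml_checkpoint`: fields `params` (selected),
#'   `last_params`, `log` (data frame epoch/loss/val_loss/lr), `pos_weight`,
#'   `config`, `d`, `N`.
#' @export
train_eml <- function(records, store, config = train_config()) {
  stopifnot(nrow(records) >= 2)
  if (any(is.na(records$label)) || !all(records$label %in% c(0L, 1L)))
    stop("training requires binary labels on every record")
  n_pos <- sum(records$label == 1); n_neg <- sum(records$label == 0)
  if (n_pos == 0 || n_neg == 0) stop("training requires both classes")
  pw <- if (identical(config$pos_weight, "auto")) n_neg / n_pos
        else config$pos_weight
  stopifnot(pw > 0)

  set.seed(config$seed)
  params <- init_eml_params(store$d, store$N,
                            bank = threshold_bank(config$n_thresholds),
                            dropout = config$dropout, tied = config$tied,
                            score_norm = config$score_norm %||% "n2")

  # validation split over epitopes for checkpoint selection
  eps <- unique(records$epitope_id)
  val_idx <- integer(0)
  if (config$val_fraction > 0 && length(eps) >= 2) {
    n_val <- max(1L, floor(config$val_fraction * length(eps)))
    n_val <- min(n_val, length(eps) - 1L)
    val_eps <- sample(eps, n_val)
    val_idx <- which(records$epitope_id %in% val_eps)
  }
  tr_idx <- setdiff(seq_len(nrow(records)), val_idx)
  blocks <- .crop_blocks(records, store)
  y <- records$label

  flat <- .flatten_params(params)
  m <- numeric(length(flat)); v <- numeric(length(flat))
  dmask <- .decay_mask(params)
  step <- 0L
  best_val <- Inf
  best_flat <- flat
  eps_c <- 1e-7
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (b in seq_len(nb)) {
      bi <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                      length(ord))]
      B <- length(bi)
      bg <- .batch_grad(blocks[bi], y[bi], pw, params, flat, config$engine)
      bloss <- bg$loss
      if (!is.finite(bloss))
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " (records ", paste(utils::head(bi, 8), collapse = ","), ")")
      ep_loss <- ep_loss + bloss * B; ep_n <- ep_n + B
      g <- bg$grad
      if (config$tied) g <- .tie_flat(g, store$d)
      gn <- sqrt(sum(g * g))
      if (is.finite(gn) && gn > config$clip_norm && gn > 0)
        g <- g * (config$clip_norm / gn)
      step <- step + 1L
      m <- config$adam_beta1 * m + (1 - config$adam_beta1) * g
      v <- config$adam_beta2 * v + (1 - config$adam_beta2) * g * g
      mhat <- m / (1 - config$adam_beta1^step)
      vhat <- v / (1 - config$adam_beta2^step)
      flat <- flat - config$learning_rate *
        (mhat / (sqrt(vhat) + config$adam_eps) +
           config$weight_decay * flat * dmask)
      params <- .unflatten_params(flat, params)
    }
    tr_loss <- ep_loss / ep_n
    val_loss <- NA_real_
    if (length(val_idx) > 0) {
      vh <- .forward_scores(blocks[val_idx], params, config$engine)
      val_loss <- eml_loss(vh, y[val_idx], pw)
      if (val_loss < best_val) { best_val <- val_loss; best_flat <- flat }
    } else {
      best_flat <- flat
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = tr_loss,
                               val_loss = val_loss,
                               lr = config$learning_rate)
  }
  structure(list(params = .unflatten_params(best_flat, params),
                 last_params = params,
                 log = do.call(rbind, log),
                 pos_weight = pw, config = config,
                 d = store$d, N = store$N,
                 n_val_records = length(val_idx)),
            class = "eml_checkpoint")
}

#' @export
print.eml_checkpoint <- function(x, ...) {
  cat("<eml_checkpoint> d=", x$d, " N=", x$N, ", ",
      nrow(x$log), " epoch(s), pos_weight=", signif(x$pos_weight, 4),
      "\n", sep = "")
  tail <- x$log[nrow(x$log), ]
  cat("  final loss ", signif(tail$loss, 5),
      if (!is.na(tail$val_loss)) paste0(", val ", signif(tail$val_loss, 5)),
      "\n", sep = "")
  invisible(x)
}

# contact_map object from a cropped prototype forward
.pad_proto <- function(pf, N, l1, l2) {
  pad <- function(mat) {
    out <- matrix(0, N, N)
    out[seq_len(nrow(mat)), seq_len(ncol(mat))] <- mat
    out
  }
  structure(list(similarity = pad(pf$S), filters = lapply(pf$Ms, pad),
                 area = pad(pf$A), score = pf$w, l1 = l1, l2 = l2),
            class = "contact_map")
}

#' Score a dataset with a trained checkpoint
#'
#' Deterministic inference (dropout disabled); the output is invariant to
#' batch size and equivariant under record reordering.
#'
#' @param records Triad data frame (labels not required).
#' @param store Embedding store covering every sequence.
#' @param checkpoint An `eml_checkpoint` (or `contact_model`).
#' @param maps If `TRUE`, also return the per-record contact maps.
#' @param batch_size Kept for interface compatibility; inference is
#'   per-record and the value does not affect results.
#' @return List with `scores` (data frame `y_hat`, `w_a`, `w_b`) and, when
#'   `maps = TRUE`, lists `map_a` and `map_b` of `contact_map` objects
#'   (peptide rows, TCR-chain columns).
#' @export
predict_dataset <- function(records, store, checkpoint, maps = FALSE,
                            batch_size = 64L) {
  params <- if (inherits(checkpoint, "contact_model"))
    checkpoint$checkpoint$params else checkpoint$params
  blocks <- .crop_blocks(records, store)
  n <- nrow(records)
  res <- cpp_batch(blocks, numeric(0), 1, .flatten_params(params),
                   params$d, params$N, params$bank$thresholds,
                   params$bank$area_weights, 0, FALSE, FALSE,
                   .norm_is_n2(params))
  out <- list(scores = data.frame(y_hat = res$y_hat, w_a = res$w_a,
                                  w_b = res$w_b))
  if (maps) {
    ma <- vector("list", n); mb <- vector("list", n)
    for (i in seq_len(n)) {
      bl <- blocks[[i]]
      fw <- .record_forward(bl$ea, bl$eb, bl$ee, params, train = FALSE)
      ma[[i]] <- .pad_proto(fw$cache$pa, params$N, nrow(bl$ee), nrow(bl$ea))
      mb[[i]] <- .pad_proto(fw$cache$pb, params$N, nrow(bl$ee), nrow(bl$eb))
    }
    out$map_a <- ma; out$map_b <- mb
  }
  out
}

#' Save / load a checkpoint
#'
#' Writes a single serialized parameter archive plus a JSON sidecar
#' (`<path>.json`) recording the architecture and decision flags needed for
#' exact reload: `d`, `N`, thresholds, area weights, dropout, tying,
#' temperature and positive-class weight.
#'
#' @param checkpoint An `eml_checkpoint`.
#' @param path Archive path.
#' @export
write_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  side <- list(d = checkpoint$d, N = checkpoint$N,
               thresholds = checkpoint$params$bank$thresholds,
               area_weights = checkpoint$params$bank$area_weights,
               dropout = checkpoint$params$dropout,
               tied = checkpoint$params$tied,
               score_norm = checkpoint$params$score_norm,
               tau = eml_tau(checkpoint$params),
               pos_weight = checkpoint$pos_weight)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
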