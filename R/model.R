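# The classic modelling surface: contact_model() fits the explainable
# binding model and returns an object with the usual methods.

#' Fit an explainable TCR-pMHC binding model
#'
#' The main entry point. Trains the cross-attention fusion stage and the
#' contact-prototype head on labelled triplet records (see [train_eml()] for
#' the regimen) and returns a fitted-model object supporting `print`,
#' `summary`, `coef`, `predict`, `plot`, `residuals` and `simulate`.
#'
#' @param data Triad data frame (columns `cdr3a`, `cdr3b`, `peptide`,
#'   `label`, `epitope_id`), e.g. from [read_triads()] or
#'   [generate_dataset()].
#' @param store An embedding store covering every sequence in `data`; built
#'   from `provider` when omitted.
#' @param provider An [embedding_provider()]; required when `store` is
#'   missing.
#' @param config A [train_config()].
#' @param ... Overrides forwarded to [train_config()] when `config` is left
#'   at its default, e.g. `epochs = 30`.
#' @return Object of class `contact_model` with fields `checkpoint` (the
#'   [train_eml()] result), `fitted` (training-set scores from the selected
#'   parameters, dropout off), `data`, `store`, `call`.
#' @examples
#' world <- generate_world(seed = 7)
#' ds <- generate_dataset(world, n_pos = 12, neg_ratio = 2)
#' fit <- contact_model(ds$records, provider = synthetic_provider(world),
#'                      epochs = 2, batch_size = 16, val_fraction = 0)
#' fit
#' head(predict(fit))
#' @export
contact_model <- function(data, store = NULL, provider = NULL,
                          config = NULL, ...) {
  cl <- match.call()
  if (is.null(config)) config <- train_config(...)
  if (is.null(store)) {
    if (is.null(provider))
      stop("supply either a prebuilt 'store' or an embedding 'provider'")
    store <- build_store(unique(c(data$cdr3a, data$cdr3b, data$peptide)),
                         provider)
  }
  ckpt <- train_eml(data, store, config)
  fitted <- predict_dataset(data, store, ckpt)$scores$y_hat
  structure(list(checkpoint = ckpt, fitted = fitted, data = data,
                 store = store, call = cl),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat("Explainable TCR-pMHC contact model\n\nCall:\n  ")
  print(x$call)
  ck <- x$checkpoint
  cat("\n", nrow(x$data), " records (",
      sum(x$data$label == 1), " positive, ", sum(x$data$label == 0),
      " negative), pos_weight ", signif(ck$pos_weight, 4), "\n", sep = "")
  cat(nrow(ck$log), " epoch(s); final train loss ",
      signif(ck$log$loss[nrow(ck$log)], 5), sep = "")
  vl <- ck$log$val_loss[nrow(ck$log)]
  if (!is.na(vl)) cat(", val loss ", signif(vl, 5), sep = "")
  cat("; tau = ", signif(eml_tau(ck$params), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.contact_model <- function(object, ...) {
  ck <- object$checkpoint
  y <- object$data$label
  s <- object$fitted
  out <- list(
    call = object$call,
    n = length(y), n_pos = sum(y == 1), n_neg = sum(y == 0),
    pos_weight = ck$pos_weight,
    epochs = nrow(ck$log),
    final_loss = ck$log$loss[nrow(ck$log)],
    best_val_loss = suppressWarnings(min(ck$log$val_loss, na.rm = TRUE)),
    tau = eml_tau(ck$params),
    score_by_class = rbind(positive = summary(s[y == 1]),
                           negative = summary(s[y == 0])),
    train_pauc = tryCatch(partial_auc(s, y, 0.1), error = function(e) NA_real_)
  )
  class(out) <- "summary.contact_model"
  out
}

#' @export
print.summary.contact_model <- function(x, ...) {
  cat("Explainable TCR-pMHC contact model\n\nCall:\n  ")
  print(x$call)
  cat("\nData: ", x$n, " records (", x$n_pos, " pos / ", x$n_neg,
      " neg), pos_weight ", signif(x$pos_weight, 4), "\n", sep = "")
  cat("Training: ", x$epochs, " epochs, final loss ",
      signif(x$final_loss, 5), sep = "")
  if (is.finite(x$best_val_loss))
    cat(", best val loss ", signif(x$best_val_loss, 5), sep = "")
  cat("\nTemperature tau: ", signif(x$tau, 4), "\n", sep = "")
  cat("\nFitted binding scores by class:\n")
  print(signif(x$score_by_class, 4))
  if (is.finite(x$train_pauc))
    cat("\nTraining partial ROC-AUC (FPR <= 0.1, standardized): ",
        signif(x$train_pauc, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.contact_model <- function(object, flatten = TRUE, ...) {
  p <- object$checkpoint$params
  if (!flatten) return(p)
  .flatten_params(p)
}

#' Predict binding scores (and contact maps) for new triplets
#'
#' @param object A fitted `contact_model`.
#' @param newdata Triad data frame; defaults to the training data.
#' @param store Embedding store covering `newdata`'s sequences; defaults to
#'   the store used at fit time.
#' @param type `"response"` for a vector of binding probabilities or
#'   `"maps"` for the full [predict_dataset()] result including per-record
#'   contact maps.
#' @param ... Unused.
#' @export
predict.contact_model <- function(object, newdata = NULL, store = NULL,
                                  type = c("response", "maps"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$data
  store <- store %||% object$store
  out <- predict_dataset(newdata, store, object$checkpoint,
                         maps = type == "maps")
  if (type == "response") out$scores$y_hat else out
}

#' @export
residuals.contact_model <- function(object, ...) {
  object$data$label - object$fitted
}

#' @export
fitted.contact_model <- function(object, ...) object$fitted

#' Simulate binding labels from the fitted probabilities
#'
#' @param object A fitted `contact_model`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed (stored on the result as with [stats::simulate]).
#' @param ... Unused.
#' @export
simulate.contact_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- pmin(pmax(object$fitted, 0), 1)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plots for a fitted contact model
#'
#' `which = 1` draws the training (and validation) loss curves; `which = 2`
#' draws the center-aligned average contact maps of the predicted positive
#' and negative classes, the summary view used to inspect what the
#' prototype head has learned.
#'
#' @param x A fitted `contact_model`.
#' @param which 1 (loss curves) or 2 (average contact maps).
#' @param threshold Score cut separating predicted classes for `which = 2`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.contact_model <- function(x, which = 1, threshold = 0.5, ...) {
  ck <- x$checkpoint
  if (which == 1) {
    graphics::plot(ck$log$epoch, ck$log$loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = "training loss", ...)
    if (any(!is.na(ck$log$val_loss)))
      graphics::lines(ck$log$epoch, ck$log$val_loss, lty = 2)
    return(invisible(x))
  }
  pr <- predict_dataset(x$data, x$store, ck, maps = TRUE)
  cls <- ifelse(pr$scores$y_hat >= threshold, "positive", "negative")
  maps <- c(pr$map_a, pr$map_b)
  avg <- center_align_average(maps, classes = c(cls, cls))
  op <- graphics::par(mfrow = c(1, length(avg)))
  on.exit(graphics::par(op))
  for (nm in names(avg))
    graphics::image(avg[[nm]]$mean, main = paste("mean contact map,", nm),
                    useRaster = TRUE, ...)
  invisible(x)
}
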