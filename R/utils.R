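# Internal helpers shared across modules.

# The 20 standard amino acids, one-letter codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' @keywords internal
softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

#' @keywords internal
inv_softplus <- function(y) {
  stopifnot(y > 0)
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate expr under a temporary RNG state; restores .Random.seed afterwards
# so deterministic sub-draws (e.g. per-sequence embedding noise) do not
# disturb the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit polynomial hash of a character string, used to give
# every sequence its own reproducible noise stream.
seq_hash <- function(s, salt = 0L) {
  h <- 7L
  m <- 2147483647
  for (code in utf8ToInt(s)) h <- as.integer((as.double(h) * 131 + code) %% m)
  as.integer((as.double(h) + as.double(salt) * 7919) %% m)
}

is_valid_aa <- function(x) {
  nchar(x) > 0 & !grepl(paste0("[^", paste(AA20, collapse = ""), "]"), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
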