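# Residue-level embedding blocks, pluggable providers, and the
# precompute-and-cache store keyed by amino-acid sequence.

#' Construct an embedding block
#'
#' An embedding block is an `N x d` matrix of per-residue embeddings for one
#' sequence, left-aligned: rows `1..L` hold residues 1..L and rows `(L+1)..N`
#' are exactly zero padding.
#'
#' @param residues `L x d` numeric matrix of per-residue embeddings
#'   (one row per residue of `sequence`).
#' @param sequence The amino-acid string encoded.
#' @param max_length Padded number of rows `N`; must be `>= L`.
#' @return An object of class `embedding_block` with fields `matrix`
#'   (`N x d`), `valid_length` and `sequence`.
#' @export
embedding_block <- function(residues, sequence, max_length) {
  residues <- as.matrix(residues)
  L <- nchar(sequence)
  if (nrow(residues) != L)
    stop("embedding rows (", nrow(residues), ") != sequence length (", L, ")")
  if (L > max_length)
    stop("sequence '", sequence, "' has length ", L,
         " exceeding max_length ", max_length,
         "; refusing to truncate silently")
  mat <- matrix(0, nrow = max_length, ncol = ncol(residues))
  mat[seq_len(L), ] <- residues
  structure(list(matrix = mat, valid_length = L, sequence = sequence),
            class = "embedding_block")
}

#' @export
print.embedding_block <- function(x, ...) {
  cat("<embedding_block> '", x$sequence, "' L=", x$valid_length,
      " N=", nrow(x$matrix), " d=", ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Logical mask of valid (non-padding) rows of a block
#' @param block An `embedding_block`.
#' @return Logical vector of length `N`.
#' @export
block_mask <- function(block) {
  seq_len(nrow(block$matrix)) <= block$valid_length
}

#' Define an embedding provider
#'
#' A provider is the abstraction over any source of per-residue embeddings
#' (an external protein language model, or the synthetic generator). It must
#' be deterministic: the same sequence always yields the same block.
#'
#' @param embed_fn Function `(sequence) -> L x d matrix` of per-residue
#'   embeddings (unpadded).
#' @param dim Embedding dimension `d`.
#' @param max_length Padded length `N` of blocks produced.
#' @param name Provider name recorded in stores.
#' @return An object of class `embedding_provider` with an `$embed(sequence)`
#'   method returning a padded [embedding_block()].
#' @export
embedding_provider <- function(embed_fn, dim, max_length, name = "custom") {
  stopifnot(is.function(embed_fn), dim >= 1, max_length >= 1)
  self <- list(dim = dim, max_length = max_length, name = name)
  self$embed <- function(sequence) {
    embedding_block(embed_fn(sequence), sequence, max_length)
  }
  structure(self, class = "embedding_provider")
}

#' Precompute embeddings for the unique sequences of a dataset
#'
#' De-duplicates the input sequences, embeds each unique sequence once with
#' the provider, and returns a store keyed by sequence string. Passing `path`
#' also serializes the store to disk; [load_store()] restores it
#' bit-identically.
#'
#' @param sequences Character vector (duplicates allowed).
#' @param provider An [embedding_provider()].
#' @param path Optional file path for on-disk persistence.
#' @return An object of class `embedding_store`.
#' @export
build_store <- function(sequences, provider, path = NULL) {
  sequences <- unique(as.character(sequences))
  too_long <- sequences[nchar(sequences) > provider$max_length]
  if (length(too_long) > 0)
    stop("sequence(s) exceed provider max_length ", provider$max_length, ": ",
         paste(utils::head(too_long, 3), collapse = ", "))
  env <- new.env(parent = emptyenv(), size = max(1L, length(sequences)))
  for (s in sequences) assign(s, provider$embed(s), envir = env)
  store <- structure(
    list(env = env, d = provider$dim, N = provider$max_length,
         provider = provider$name, created = format(Sys.time(), tz = "UTC")),
    class = "embedding_store")
  if (!is.null(path)) save_store(store, path)
  store
}

#' @export
print.embedding_store <- function(x, ...) {
  cat("<embedding_store> ", length(ls(x$env)), " unique sequence(s), d=",
      x$d, " N=", x$N, " provider=", x$provider, "\n", sep = "")
  invisible(x)
}

#' Number of unique sequences held by a store
#' @param store An `embedding_store`.
#' @export
store_size <- function(store) length(ls(store$env))

#' Look up the embedding block of one sequence
#' @param store An `embedding_store`.
#' @param sequence Amino-acid string.
#' @export
store_lookup <- function(store, sequence) {
  if (!exists(sequence, envir = store$env, inherits = FALSE))
    stop("sequence not in embedding store: '", sequence, "'")
  get(sequence, envir = store$env, inherits = FALSE)
}

#' Serialize / restore an embedding store
#'
#' The on-disk form is a single archive holding one matrix per unique
#' sequence plus the global attributes (provider name, `d`, `N`, creation
#' time); the round trip is bit-identical.
#'
#' @param store An `embedding_store`.
#' @param path File path.
#' @export
save_store <- function(store, path) {
  keys <- ls(store$env)
  blocks <- mget(keys, envir = store$env)
  saveRDS(list(blocks = blocks, d = store$d, N = store$N,
               provider = store$provider, created = store$created),
          path)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  x <- readRDS(path)
  env <- new.env(parent = emptyenv())
  for (k in names(x$blocks)) assign(k, x$blocks[[k]], envir = env)
  structure(list(env = env, d = x$d, N = x$N, provider = x$provider,
                 created = x$created),
            class = "embedding_store")
}

#' Assemble aligned embedding batches for a set of records
#'
#' Retrieves the cached blocks of each record's CDR3 alpha, CDR3 beta and
#' peptide sequences, preserving record order: record `i` maps to element
#' `i` of each of the three batch lists and to row `i` of each mask matrix.
#'
#' @param records Triad data frame.
#' @param store An `embedding_store` covering every sequence in `records`.
#' @return List with elements `a`, `b`, `e`, each a list of
#'   `embedding_block`s, and `mask_a`, `mask_b`, `mask_e`, logical
#'   `B x N` matrices marking valid positions.
#' @export
assemble_batch <- function(records, store) {
  grab <- function(seqs) lapply(seqs, function(s) store_lookup(store, s))
  a <- grab(records$cdr3a); b <- grab(records$cdr3b); e <- grab(records$peptide)
  msk <- function(blocks) {
    do.call(rbind, lapply(blocks, block_mask))
  }
  list(a = a, b = b, e = e,
       mask_a = msk(a), mask_b = msk(b), mask_e = msk(e))
}
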