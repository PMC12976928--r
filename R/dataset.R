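# Reading, validating, negatively augmenting and splitting paired-chain
# TCR-pMHC triplet datasets.

#' Read a TCR-pMHC triplet table
#'
#' Reads a delimited text file of paired-chain TCR records (CDR3 alpha,
#' CDR3 beta, peptide, optional binary label) and returns a validated triad
#' data frame. Sequences are uppercased before validation; rows containing
#' characters outside the 20 standard one-letter amino-acid codes (or empty
#' sequences) are dropped and the number of dropped rows is reported via a
#' message and the `"n_dropped"` attribute.
#'
#' @param path Path to a CSV or TSV file.
#' @param column_map Named character vector mapping the logical column names
#'   `cdr3a`, `cdr3b`, `peptide` (required) and `label`, `epitope_id`,
#'   `source`, `mhc_class` (optional) to the file's column names. Logical
#'   names already present in the file need not be mapped.
#' @param delim Field delimiter; defaults to `","` for `.csv` and `"\t"`
#'   otherwise.
#' @param require_label If `TRUE` (default) a label column must be present;
#'   set `FALSE` for prediction-only input.
#' @return A `data.frame` with columns `cdr3a`, `cdr3b`, `peptide`, `label`
#'   (integer 0/1, `NA` when absent), `epitope_id` (defaults to the peptide
#'   sequence), `source`, `mhc_class` and `provenance`.
#' @seealso [write_triads()], [generate_negatives()], [unseen_epitope_split()]
#' @export
read_triads <- function(path, column_map = NULL, delim = NULL,
                        require_label = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  pick <- function(logical_name) {
    nm <- if (!is.null(column_map) && logical_name %in% names(column_map))
      column_map[[logical_name]] else logical_name
    if (!nm %in% names(raw)) return(NULL)
    raw[[nm]]
  }
  for (req in c("cdr3a", "cdr3b", "peptide")) {
    if (is.null(pick(req)))
      stop("required column '", req, "' not found in ", path,
           " (check column_map)")
  }
  lab <- pick("label")
  if (is.null(lab)) {
    if (require_label) stop("required column 'label' not found in ", path)
    lab <- rep(NA_integer_, nrow(raw))
  }
  df <- data.frame(
    cdr3a = toupper(trimws(as.character(pick("cdr3a")))),
    cdr3b = toupper(trimws(as.character(pick("cdr3b")))),
    peptide = toupper(trimws(as.character(pick("peptide")))),
    label = suppressWarnings(as.integer(lab)),
    stringsAsFactors = FALSE
  )
  df$epitope_id <- {
    e <- pick("epitope_id")
    if (is.null(e)) df$peptide else as.character(e)
  }
  df$source <- { s <- pick("source"); if (is.null(s)) "unknown" else as.character(s) }
  df$mhc_class <- {
    m <- pick("mhc_class")
    if (is.null(m)) "unknown" else as.character(m)
  }
  df$provenance <- { p <- pick("provenance"); if (is.null(p)) "positive" else as.character(p) }

  ok <- is_valid_aa(df$cdr3a) & is_valid_aa(df$cdr3b) & is_valid_aa(df$peptide)
  if (!all(is.na(df$label))) ok <- ok & (is.na(df$label) | df$label %in% c(0L, 1L))
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_triads: dropped ", n_dropped,
            " row(s) with non-standard or missing residues")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("empty dataset: no valid rows remain in ", path)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write a triad data frame back to delimited text
#'
#' Inverse of [read_triads()]; reading the written file yields an identical
#' record list (idempotent round trip).
#'
#' @param triads Triad data frame.
#' @param path Output path.
#' @param delim Field delimiter; defaults by file extension as in
#'   [read_triads()].
#' @export
write_triads <- function(triads, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(triads, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Generate shuffled negative records
#'
#' For each epitope, emits `floor(ratio * n_positives)` negative records whose
#' paired (cdr3a, cdr3b) chains are drawn together from a record of a
#' different epitope and whose peptide is the target epitope's peptide. No
#' emitted negative duplicates a known positive (cdr3a, cdr3b, peptide)
#' triple; collisions are resolved by rejection sampling with a bounded retry
#' count, after which the shortfall is reported. Repeated negatives are
#' permitted (small epitope sets may not admit enough distinct pairings).
#'
#' @param positives Triad data frame of positive records (label 1).
#' @param ratio Positive real; negatives per positive (the canonical
#'   imbalance is 4:1).
#' @param seed Integer seed; generation is deterministic under a fixed seed.
#' @param max_retries Retries per draw before a shortfall is declared.
#' @return Data frame of negative records (label 0, provenance
#'   `"shuffled-negative"`), with attribute `"shortfall"` (named integer per
#'   epitope) when quotas could not be met.
#' @export
generate_negatives <- function(positives, ratio = 4, seed = 1L,
                               max_retries = 100L) {
  if (ratio <= 0) stop("ratio must be positive")
  eps <- unique(positives$epitope_id)
  if (length(eps) < 2)
    stop("negative generation needs at least 2 distinct epitopes; got ",
         length(eps))
  pos_key <- paste(positives$cdr3a, positives$cdr3b, positives$peptide,
                   sep = "\r")
  out <- vector("list", length(eps))
  shortfall <- integer(0)
  with_seed(seed, {
    for (i in seq_along(eps)) {
      e <- eps[i]
      tgt <- positives[positives$epitope_id == e, , drop = FALSE]
      donors <- positives[positives$epitope_id != e, , drop = FALSE]
      quota <- floor(ratio * nrow(tgt))
      rows <- vector("list", quota)
      got <- 0L
      while (got < quota) {
        emitted <- FALSE
        for (try in seq_len(max_retries)) {
          t_row <- tgt[sample.int(nrow(tgt), 1L), ]
          d_row <- donors[sample.int(nrow(donors), 1L), ]
          key <- paste(d_row$cdr3a, d_row$cdr3b, t_row$peptide, sep = "\r")
          if (!(key %in% pos_key)) {
            got <- got + 1L
            rows[[got]] <- data.frame(
              cdr3a = d_row$cdr3a, cdr3b = d_row$cdr3b,
              peptide = t_row$peptide, label = 0L,
              epitope_id = e, source = t_row$source,
              mhc_class = t_row$mhc_class,
              provenance = "shuffled-negative",
              stringsAsFactors = FALSE)
            emitted <- TRUE
            break
          }
        }
        if (!emitted) { # exhausted retries for this slot
          shortfall[e] <- quota - got
          break
        }
      }
      out[[i]] <- if (got > 0) do.call(rbind, rows[seq_len(got)]) else NULL
    }
  })
  negs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(negs))
    negs <- positives[0, c("cdr3a", "cdr3b", "peptide", "label", "epitope_id",
                           "source", "mhc_class", "provenance")]
  rownames(negs) <- NULL
  if (length(shortfall) > 0) {
    warning("generate_negatives: shortfall of ", sum(shortfall),
            " negative(s) across ", length(shortfall), " epitope(s)")
    attr(negs, "shortfall") <- shortfall
  }
  negs
}

#' Split a dataset by unseen epitopes with a Levenshtein guarantee
#'
#' Selects test epitopes from those whose minimal Levenshtein distance to
#' every other epitope's peptide exceeds `min_edit_distance`, so that every
#' test/train epitope pair is guaranteed to be more than the threshold apart.
#' The split fraction is applied at the epitope level, since the protocol
#' defines the test set as epitopes absent from training.
#'
#' @param records Triad data frame.
#' @param min_edit_distance Non-negative integer edit-distance threshold; the
#'   split guarantees distance strictly greater than this value.
#' @param test_fraction Fraction of epitopes assigned to the test set, in
#'   (0,1).
#' @param seed Integer seed for epitope sampling.
#' @return List with elements `train` and `test` (triad data frames) and
#'   attributes `train_epitopes` / `test_epitopes`.
#' @export
unseen_epitope_split <- function(records, min_edit_distance = 3L,
                                 test_fraction = 0.05, seed = 1L) {
  stopifnot(min_edit_distance >= 0, test_fraction > 0, test_fraction < 1)
  eps <- unique(records$epitope_id)
  if (length(eps) < 2) stop("split needs at least 2 distinct epitopes")
  # one representative peptide per epitope id
  pep <- records$peptide[match(eps, records$epitope_id)]
  D <- utils::adist(pep)
  diag(D) <- NA
  min_d <- apply(D, 1, min, na.rm = TRUE)
  eligible <- which(min_d > min_edit_distance)
  if (length(eligible) == 0)
    stop("infeasible split: no epitope has minimal Levenshtein distance > ",
         min_edit_distance, " to all others")
  n_test <- max(1L, round(test_fraction * length(eps)))
  if (length(eligible) < n_test) {
    warning("unseen_epitope_split: only ", length(eligible),
            " epitope(s) satisfy the threshold; test set smaller than requested")
    n_test <- length(eligible)
  }
  if (n_test >= length(eps))
    stop("infeasible split: all epitopes would land in the test set at ",
         "threshold ", min_edit_distance)
  test_idx <- with_seed(seed,
                        eligible[sample.int(length(eligible), n_test)])
  test_eps <- eps[test_idx]
  train_eps <- setdiff(eps, test_eps)
  # exhaustive guarantee check over all test x train pairs
  chk <- utils::adist(pep[test_idx], pep[match(train_eps, eps)])
  stopifnot(all(chk > min_edit_distance))
  out <- list(
    train = records[records$epitope_id %in% train_eps, , drop = FALSE],
    test  = records[records$epitope_id %in% test_eps, , drop = FALSE]
  )
  rownames(out$train) <- rownames(out$test) <- NULL
  attr(out, "train_epitopes") <- train_eps
  attr(out, "test_epitopes") <- test_eps
  out
}
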