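# Evaluation: partial ROC-AUC under a false-positive-rate cap, Binding
# Region Hit Rate against structure-derived residue distances, and
# center-aligned contact-map averaging.

#' Partial ROC-AUC with a false-positive-rate cap
#'
#' Area under the ROC curve restricted to `FPR <= max_fpr`, built by sorting
#' scores, collapsing ties into single ROC vertices, trapezoidal
#' integration, and linear interpolation at the cap. With
#' `standardize = TRUE` the area is McClish-transformed so a perfect
#' classifier scores 1 and chance scores 0.5 regardless of the cap.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @param max_fpr Cap on the false positive rate, in (0, 1].
#' @param standardize Apply the McClish correction (default `TRUE`).
#' @return Scalar AUC.
#' @export
partial_auc <- function(scores, labels, max_fpr = 0.1, standardize = TRUE) {
  stopifnot(length(scores) == length(labels), max_fpr > 0, max_fpr <= 1)
  labels <- as.integer(labels)
  P <- sum(labels == 1); Ng <- sum(labels == 0)
  if (P == 0 || Ng == 0)
    stop("partial_auc undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse tied scores into single ROC vertices
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / Ng)
  # clip the curve at max_fpr with linear interpolation
  keep <- fpr <= max_fpr
  xk <- fpr[keep]; yk <- tpr[keep]
  if (max(xk) < max_fpr && any(fpr > max_fpr)) {
    i <- which(fpr > max_fpr)[1]
    x0 <- fpr[i - 1]; y0 <- tpr[i - 1]
    frac <- (max_fpr - x0) / (fpr[i] - x0)
    xk <- c(xk, max_fpr); yk <- c(yk, y0 + frac * (tpr[i] - y0))
  }
  pauc <- sum(diff(xk) * (utils::head(yk, -1) + utils::tail(yk, -1)) / 2)
  if (!standardize) return(pauc)
  amin <- max_fpr^2 / 2
  amax <- max_fpr
  0.5 * (1 + (pauc - amin) / (amax - amin))
}

#' Per-residue importance scores from a contact map
#'
#' Reduces the contact-area map `A'` along the partner axis to one score per
#' source residue, restricted to valid positions. The default reduction is
#' the maximum, mirroring the nearest-atom (minimum-distance) convention of
#' the structural ground truth; a mean reduction is available.
#'
#' @param map A `contact_map` (peptide rows, TCR-chain columns).
#' @param axis `"tcr"` to score TCR-chain residues (reduce over peptide
#'   partners) or `"peptide"` to score peptide residues.
#' @param reduce `"max"` (default) or `"mean"`.
#' @return Numeric vector of length `l2` (`"tcr"`) or `l1` (`"peptide"`).
#' @export
residue_importance <- function(map, axis = c("tcr", "peptide"),
                               reduce = c("max", "mean")) {
  axis <- match.arg(axis); reduce <- match.arg(reduce)
  A <- map$area[seq_len(map$l1), seq_len(map$l2), drop = FALSE]
  f <- if (reduce == "max") max else mean
  if (axis == "tcr") apply(A, 2, f) else apply(A, 1, f)
}

#' Binding Region Hit Rate
#'
#' Compares the top `t` fraction of residues ranked by model contact score
#' with the top `t` fraction ranked by structural proximity (smallest
#' distance). With `k = max(1, ceiling(t * L))` — at least one contact
#' residue per case — the hit rate is `|intersection| / k`. Ties are broken
#' stably by ascending residue index.
#'
#' @param scores Per-residue importance scores (higher = more important).
#' @param distances Per-residue distances in Angstrom (smaller = closer), a
#'   numeric vector or a `distance_map` from [residue_distances()].
#' @param t Fraction in (0, 1]; the reference protocol uses 0.25.
#' @return List with `hit_rate`, `n_selected` (`k`), `t` and `L`.
#' @export
brhr <- function(scores, distances, t = 0.25) {
  if (is.list(distances) && !is.null(distances$distances))
    distances <- distances$distances
  L <- length(scores)
  if (L != length(distances))
    stop("scores (", L, ") and distances (", length(distances),
         ") differ in length")
  stopifnot(t > 0, t <= 1, L >= 1)
  k <- max(1L, ceiling(t * L))
  top_model <- order(-scores, seq_len(L))[seq_len(k)]
  top_truth <- order(distances, seq_len(L))[seq_len(k)]
  list(hit_rate = length(intersect(top_model, top_truth)) / k,
       n_selected = k, t = t, L = L)
}

#' Residue-to-partner nearest-atom distances from a structure
#'
#' For a TCR-pMHC structure in PDB format, computes for every residue of
#' each selection the Euclidean distance to the nearest atom of the partner
#' selection, in all four directions (peptide -> CDR3a, peptide -> CDR3b,
#' CDR3a -> peptide, CDR3b -> peptide). Hydrogens are excluded and alternate
#' locations other than '' / 'A' are dropped, following standard structural
#' conventions. Residues missing inside a requested range are reported in
#' the `"gaps"` attribute.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param peptide_chain Chain identifier of the presented peptide.
#' @param cdr3a,cdr3b Lists `list(chain = , resno = )` giving the chain id
#'   and the (author-numbered) residue interval of each CDR3 loop, e.g.
#'   `list(chain = "D", resno = 105:117)`.
#' @return Named list of four `distance_map` objects (`pep_to_cdr3a`,
#'   `pep_to_cdr3b`, `cdr3a_to_pep`, `cdr3b_to_pep`), each with fields
#'   `direction`, `distances` (named by residue number) and `source_ids`.
#' @export
residue_distances <- function(pdb, peptide_chain, cdr3a, cdr3b) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  keep <- at$alt %in% c("", "A", NA)
  elesy <- if ("elesy" %in% names(at)) at$elesy else NA
  hyd <- if (all(is.na(elesy))) grepl("^[0-9]*H", at$elety)
         else elesy %in% "H"
  at <- at[keep & !hyd, , drop = FALSE]
  sel <- function(chain, resno = NULL) {
    r <- at[at$chain == chain, , drop = FALSE]
    if (!is.null(resno)) r <- r[r$resno %in% resno, , drop = FALSE]
    if (nrow(r) == 0)
      stop("selection resolves to no atoms: chain ", chain,
           if (!is.null(resno)) paste0(" resno ", min(resno), "-", max(resno)))
    r
  }
  pep <- sel(peptide_chain)
  ca <- sel(cdr3a$chain, cdr3a$resno)
  cb <- sel(cdr3b$chain, cdr3b$resno)
  gaps <- list(
    cdr3a = if (!is.null(cdr3a$resno)) setdiff(cdr3a$resno, unique(ca$resno))
            else integer(0),
    cdr3b = if (!is.null(cdr3b$resno)) setdiff(cdr3b$resno, unique(cb$resno))
            else integer(0))
  xyz <- function(r) cbind(r$x, r$y, r$z)
  per_residue_min <- function(src, tgt) {
    tx <- xyz(tgt)
    res <- unique(src$resno)
    d <- vapply(res, function(rn) {
      sx <- xyz(src[src$resno == rn, , drop = FALSE])
      # nearest atom over all atom pairs of this residue vs the target
      min(sqrt(outer(rowSums(sx^2), rowSums(tx^2), `+`) -
                 2 * sx %*% t(tx)))
    }, numeric(1))
    d[d < 0] <- 0 # numerical guard
    stats::setNames(d, res)
  }
  dm <- function(direction, src, tgt) {
    d <- per_residue_min(src, tgt)
    structure(list(direction = direction, distances = d,
                   source_ids = as.integer(names(d))),
              class = "distance_map")
  }
  out <- list(pep_to_cdr3a = dm("pep_to_cdr3a", pep, ca),
              pep_to_cdr3b = dm("pep_to_cdr3b", pep, cb),
              cdr3a_to_pep = dm("cdr3a_to_pep", ca, pep),
              cdr3b_to_pep = dm("cdr3b_to_pep", cb, pep))
  attr(out, "gaps") <- gaps
  if (length(gaps$cdr3a) > 0 || length(gaps$cdr3b) > 0)
    warning("missing residues inside requested range(s): ",
            paste(unlist(gaps), collapse = ","))
  out
}

#' @export
print.distance_map <- function(x, ...) {
  cat("<distance_map> ", x$direction, ": ", length(x$distances),
      " residue(s), min ", signif(min(x$distances), 4), " A\n", sep = "")
  invisible(x)
}

#' Center-aligned average of contact maps
#'
#' Sequences differ in length, so before averaging, each map's valid
#' `l1 x l2` block is re-placed so that it is centered in the padded `N x N`
#' frame (offset `floor((N - l) / 2)` per axis). Returns the elementwise
#' mean and variance; when `classes` is given, one mean/variance pair per
#' class.
#'
#' @param maps List of `contact_map` objects (or plain `N x N` matrices, in
#'   which case `lengths` must supply the valid block sizes).
#' @param lengths Optional list of `c(l1, l2)` per map.
#' @param classes Optional grouping vector (e.g. predicted class) of the
#'   same length as `maps`.
#' @return List with `mean`, `var` and `n`; or a named list of such lists,
#'   one per class.
#' @export
center_align_average <- function(maps, lengths = NULL, classes = NULL) {
  if (!is.null(classes)) {
    stopifnot(length(classes) == length(maps))
    gs <- split(seq_along(maps), classes)
    return(lapply(gs, function(ix)
      center_align_average(maps[ix], lengths[ix])))
  }
  stopifnot(length(maps) >= 1)
  getm <- function(i) if (inherits(maps[[i]], "contact_map")) maps[[i]]$area
                      else as.matrix(maps[[i]])
  getl <- function(i) {
    if (!is.null(lengths)) return(lengths[[i]])
    c(maps[[i]]$l1, maps[[i]]$l2)
  }
  N <- nrow(getm(1))
  acc <- matrix(0, N, N); acc2 <- matrix(0, N, N)
  for (i in seq_along(maps)) {
    m <- getm(i); l <- getl(i)
    o1 <- floor((N - l[1]) / 2); o2 <- floor((N - l[2]) / 2)
    cen <- matrix(0, N, N)
    cen[o1 + seq_len(l[1]), o2 + seq_len(l[2])] <-
      m[seq_len(l[1]), seq_len(l[2])]
    acc <- acc + cen
    acc2 <- acc2 + cen^2
  }
  n <- length(maps)
  mu <- acc / n
  list(mean = mu, var = if (n > 1) (acc2 - n * mu^2) / (n - 1)
                        else matrix(0, N, N),
       n = n)
}
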