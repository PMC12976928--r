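# helper: write a minimal PDB file from an atom table
write_pdb_fixture <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$name, a$res, a$chain, a$resno, a$x, a$y, a$z, 1.0, 0.0,
            a$elem)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

atom_row <- function(chain, resno, x, y = 0, z = 0, name = "CA",
                     elem = "C", res = "ALA") {
  data.frame(chain = chain, resno = resno, x = x, y = y, z = z, name = name,
             elem = elem, res = res, stringsAsFactors = FALSE)
}

test_that("nearest-atom distances follow the min rule in both directions", {
  atoms <- rbind(
    atom_row("P", 1, 0),            # peptide residue
    atom_row("A", 10, 4),           # single-atom CDR3a residue, 4 A away
    atom_row("A", 11, 3, name = "CB"),  # CDR3a residue with atoms at 3 A
    atom_row("A", 11, 6),               # ... and 6 A
    atom_row("B", 20, 0, y = 5))    # CDR3b residue, 5 A away
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(atoms, f)
  dm <- residue_distances(f, peptide_chain = "P",
                          cdr3a = list(chain = "A", resno = 10:11),
                          cdr3b = list(chain = "B", resno = 20))
  expect_equal(unname(dm$cdr3a_to_pep$distances), c(4, 3)) # nearest atom
  expect_equal(unname(dm$pep_to_cdr3a$distances), 3)
  expect_equal(unname(dm$pep_to_cdr3b$distances), 5)
  expect_equal(unname(dm$cdr3b_to_pep$distances), 5)
  expect_equal(dm$cdr3a_to_pep$source_ids, c(10L, 11L))
})

test_that("hydrogens are excluded and unresolvable selections are named errors", {
  atoms <- rbind(
    atom_row("P", 1, 0),
    atom_row("A", 10, 4),
    atom_row("A", 10, 1, name = "H", elem = "H")) # hydrogen, closer
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(atoms, f)
  dm <- residue_distances(f, "P", cdr3a = list(chain = "A", resno = 10),
                          cdr3b = list(chain = "A", resno = 10))
  expect_equal(unname(dm$cdr3a_to_pep$distances), 4) # not 1
  expect_error(residue_distances(f, "P",
                                 cdr3a = list(chain = "Z", resno = 1),
                                 cdr3b = list(chain = "A", resno = 10)),
               "chain Z")
  # missing residues inside the range are reported as gaps
  expect_warning(
    dg <- residue_distances(f, "P", cdr3a = list(chain = "A", resno = 9:10),
                            cdr3b = list(chain = "A", resno = 10)),
    "missing residues")
  expect_equal(attr(dg, "gaps")$cdr3a, 9L)
})

test_that("a toy structure matches an all-pairs atom-loop oracle and is atom-symmetric", {
  set.seed(21)
  u3 <- function() round(runif(1, 0, 8), 3) # PDB stores 3 decimals
  pep <- do.call(rbind, lapply(1:5, function(r)
    atom_row("P", r, u3(), u3(), u3())))
  pep2 <- do.call(rbind, lapply(1:5, function(r)
    atom_row("P", r, u3(), u3(), u3(), name = "CB")))
  cdr <- do.call(rbind, lapply(11:14, function(r)
    atom_row("A", r, u3(), u3(), u3())))
  atoms <- rbind(pep, pep2, cdr)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(atoms, f)
  dm <- residue_distances(f, "P", cdr3a = list(chain = "A", resno = 11:14),
                          cdr3b = list(chain = "A", resno = 11:14))
  # brute-force atom enumeration
  dist1 <- function(a, b) sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  pp <- rbind(pep, pep2)
  for (r in 1:5) {
    best <- Inf
    for (i in which(pp$resno == r)) for (j in seq_len(nrow(cdr)))
      best <- min(best, dist1(pp[i, ], cdr[j, ]))
    expect_equal(unname(dm$pep_to_cdr3a$distances[r]), best, tolerance = 1e-6)
  }
  for (k in seq_along(11:14)) {
    best <- Inf
    for (i in seq_len(nrow(pp)))
      best <- min(best, dist1(pp[i, ], cdr[k, ]))
    expect_equal(unname(dm$cdr3a_to_pep$distances[k]), best, tolerance = 1e-6)
  }
  # global atom-level minimum is direction-independent
  expect_equal(min(dm$pep_to_cdr3a$distances), min(dm$cdr3a_to_pep$distances),
               tolerance = 1e-9)
})

test_that("residue importance reduces the area map along the partner axis", {
  A <- matrix(0, 8, 8)
  A[1:6, 3] <- c(0.1, 0.9, 0.3, 0.5, 0.2, 0.4) # one nonzero TCR column
  map <- structure(list(area = A, l1 = 6, l2 = 7), class = "contact_map")
  sc <- residue_importance(map, axis = "tcr")
  expect_length(sc, 7)
  expect_equal(sc[3], 0.9)
  expect_equal(sc[-3], rep(0, 6))
  # every peptide residue's score equals its entry in that column
  expect_equal(residue_importance(map, axis = "peptide"), A[1:6, 3])
  # random map vs double-loop max oracle
  set.seed(22)
  A2 <- matrix(runif(64), 8, 8)
  map2 <- structure(list(area = A2, l1 = 6, l2 = 7), class = "contact_map")
  ref <- numeric(7)
  for (j in 1:7) {
    ref[j] <- -Inf
    for (k in 1:6) ref[j] <- max(ref[j], A2[k, j])
  }
  expect_equal(residue_importance(map2, axis = "tcr"), ref)
  expect_equal(residue_importance(map2, axis = "peptide", reduce = "mean"),
               rowMeans(A2[1:6, 1:7]))
})

test_that("BRHR is 1 for perfect explanations and k respects the at-least-one rule", {
  d <- c(9.1, 3.2, 12.0, 4.5, 8.8, 15.0, 3.9, 10.2)
  r <- brhr(-d, d, t = 0.25) # scores exactly inverse to distances
  expect_equal(r$hit_rate, 1.0)
  expect_equal(r$n_selected, 2)
  expect_equal(brhr(c(1, 2, 3, 4), c(4, 3, 2, 1), t = 0.25)$n_selected, 1)
  expect_error(brhr(1:3, 1:4), "length")
  # stable tie-break by ascending residue index
  expect_equal(brhr(rep(0, 8), c(5, 1, 9, 9, 9, 9, 9, 0.5), t = 0.25)$hit_rate,
               0.5) # model picks {1,2}; truth {8,2}; overlap {2}
})

test_that("BRHR of a random ranking is calibrated to t on average", {
  set.seed(23)
  n <- 2e4
  hits <- vapply(seq_len(n), function(i)
    brhr(runif(8), runif(8), t = 0.25)$hit_rate, numeric(1))
  # hypergeometric null: mean k/L = 0.25
  k <- 2; L <- 8
  v <- (k / L) * (1 - k / L) * (L - k) / (L - 1) / k
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(v / n))
})

test_that("partial AUC has the documented fixed points and matches oracles", {
  y <- c(rep(1, 10), rep(0, 20))
  expect_equal(partial_auc(c(rnorm(10) + 100, rnorm(20)), y, 0.1), 1.0)
  expect_equal(partial_auc(rep(0.7, 30), y, 0.1), 0.5)
  expect_error(partial_auc(1:5, rep(1, 5), 0.1), "both classes")
  expect_error(partial_auc(1:4, c(0, 1, 0, 1), 0), "max_fpr")
  # cap 1 equals the full ROC-AUC (pair-counting oracle), ties included
  set.seed(24)
  for (rep in 1:5) {
    s <- round(rnorm(40), 1) # coarse scores force ties
    yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    expect_lt(abs(partial_auc(s, yy, max_fpr = 1) - auc_pairs_oracle(s, yy)),
              1e-9)
  }
})

test_that("partial AUC on 30-point toys matches an independent ROC construction", {
  skip_if_not_installed("pROC")
  set.seed(25)
  n_checked <- 0
  for (rep in 1:8) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(30) + y # informative scores keep the capped area above chance
    ref <- suppressWarnings(as.numeric(
      pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                partial.auc = c(1, 0.9),
                partial.auc.focus = "specificity",
                partial.auc.correct = TRUE)))
    if (is.na(ref)) next # pROC declines below-chance corrected areas
    expect_equal(partial_auc(s, y, 0.1), ref, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 3)
})

test_that("center alignment places valid blocks centrally before averaging", {
  # single map with full-length block: averaging is the identity
  set.seed(26)
  m <- matrix(runif(36), 6, 6)
  one <- center_align_average(list(m), lengths = list(c(6, 6)))
  expect_equal(one$mean, m)
  expect_equal(one$var, matrix(0, 6, 6))
  # two all-ones blocks of different sizes: 1 in the overlap, 0.5 where one
  m1 <- matrix(1, 6, 6)
  m2 <- matrix(0, 6, 6); m2[1:2, 1:2] <- 1
  two <- center_align_average(list(m1, m2), lengths = list(c(6, 6), c(2, 2)))
  expect_equal(two$mean[3:4, 3:4], matrix(1, 2, 2))
  expect_equal(two$mean[1:2, 1:2], matrix(0.5, 2, 2))
  expect_equal(sum(two$mean), (36 + 4) / 2)
})

test_that("center-aligned averaging matches a loop-based placement oracle", {
  set.seed(27)
  N <- 8
  maps <- list(); lens <- list()
  for (i in 1:20) {
    l <- sample(3:8, 2, replace = TRUE)
    m <- matrix(0, N, N)
    m[seq_len(l[1]), seq_len(l[2])] <- runif(l[1] * l[2])
    maps[[i]] <- m; lens[[i]] <- l
  }
  got <- center_align_average(maps, lengths = lens)
  acc <- matrix(0, N, N)
  for (i in 1:20) {
    o1 <- floor((N - lens[[i]][1]) / 2); o2 <- floor((N - lens[[i]][2]) / 2)
    for (r in seq_len(lens[[i]][1])) for (cc in seq_len(lens[[i]][2]))
      acc[o1 + r, o2 + cc] <- acc[o1 + r, o2 + cc] + maps[[i]][r, cc]
  }
  expect_equal(got$mean, acc / 20, tolerance = 1e-12)
  expect_equal(got$n, 20)
  # grouping by class returns one average per class
  cls <- rep(c("pos", "neg"), 10)
  grouped <- center_align_average(maps, lengths = lens, classes = cls)
  expect_named(grouped, c("neg", "pos"))
  expect_equal(grouped$pos$n, 10)
})
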