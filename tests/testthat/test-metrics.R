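# Conservation calls, gap/SS statistics, superposition and dissimilarity.

make_alignment <- function(rows) {
  ids <- names(rows)
  p <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), unlist(rows))), p)
  sts <- lapply(ids, function(id) {
    aa1 <- gsub("-", "", rows[[id]])
    n <- nchar(aa1)
    ca_structure(id, cbind(seq_len(n) * 3.8, 0, 0),
                 aa = vapply(strsplit(aa1, "")[[1]], bio3d::aa123, character(1)))
  })
  names(sts) <- ids
  list(a = read_alignment(p, sts), structures = sts)
}

test_that("fully identical occupied columns are ACR; a single gap demotes to HCR", {
  rows <- list(m1 = "AC", m2 = "AC", m3 = "AC", m4 = "AC", m5 = "A-")
  x <- make_alignment(rows)
  prof <- conservation_profile(x$a)
  expect_equal(prof$profile$class[1], "ACR")
  expect_equal(prof$profile$class[2], "HCR")     # 4/5 = 0.8, gap counts against
  expect_equal(prof$profile$fraction[2], 0.8)
  expect_false(2 %in% prof$acr_columns)
  expect_true(all(prof$profile$occupancy[prof$acr_columns] == 1))
})

test_that("conservation calls match a per-column counting oracle on random alignments", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:8, 1); L <- sample(5:15, 1)
    chars <- c("A", "C", "D", "-")
    m <- matrix(sample(chars, n * L, replace = TRUE, prob = c(.4, .25, .2, .15)),
                nrow = n)
    # keep no column all-gap and rows non-empty
    m[1, ] <- ifelse(colSums(m != "-") == 0, "A", m[1, ])
    rows <- apply(m, 1, paste, collapse = "")
    if (any(!grepl("[^-]", rows))) next
    names(rows) <- paste0("m", seq_len(n))
    x <- make_alignment(as.list(rows))
    prof <- conservation_profile(x$a)
    for (c in seq_len(L)) {
      col <- x$a$ali[, c]
      tab <- table(col[col != "-"])
      frac <- if (length(tab)) max(tab) / n else 0
      expected <- if (frac == 1 && all(col != "-")) "ACR"
                  else if (frac >= 0.8 && frac < 1) "HCR" else "."
      expect_equal(prof$profile$class[c], expected)
    }
  }
})

test_that("lowering the HCR threshold only grows the HCR set", {
  fx <- generate_fixture(fixture_spec(n_members = 5, base_length = 20, seed = 3))
  h80 <- conservation_profile(fx$alignment, hcr_low = 0.8)$hcr_columns
  h60 <- conservation_profile(fx$alignment, hcr_low = 0.6)$hcr_columns
  expect_true(all(h80 %in% h60))
})

test_that("gap percentages are plain character counts", {
  x <- make_alignment(list(m1 = "A---", m2 = "ACDW"))
  g <- gap_stats(x$a)
  expect_equal(unname(g$per_member["m1"]), 75)
  expect_equal(unname(g$per_member["m2"]), 0)
  expect_equal(g$mean, 37.5)
  fx <- generate_fixture(fixture_spec(n_members = 4, base_length = 15, seed = 9))
  g2 <- gap_stats(fx$alignment)
  expect_equal(unname(g2$per_member),
               unname(100 * rowSums(fx$alignment$ali == "-") /
                        fx$alignment$n_columns))
})

test_that("SS conservation requires full occupancy and unanimity", {
  x <- make_alignment(list(m1 = "ACD", m2 = "ACD"))
  allH <- ss_conservation(x$a, list(m1 = "HHH", m2 = "HHH"))
  expect_equal(allH$percent, 100)
  mixed <- ss_conservation(x$a, list(m1 = "HHH", m2 = "CCC"))
  expect_equal(mixed$percent, 0)
  # gap column: not conserved even where present members agree
  y <- make_alignment(list(m1 = "ACD", m2 = "A-D"))
  ssc <- ss_conservation(y$a, list(m1 = "HHH", m2 = "HH"))
  expect_equal(ssc$conserved_columns, c(1L, 3L))
  expect_error(ss_conservation(x$a, list(m1 = "HH", m2 = "HHH")),
               class = "psnalign_consistency_error")
})

test_that("majority SS rule is laxer than unanimity", {
  x <- make_alignment(list(m1 = "AC", m2 = "AC", m3 = "AC"))
  ss <- list(m1 = "HH", m2 = "HH", m3 = "HC")
  expect_equal(ss_conservation(x$a, ss)$percent, 50)
  expect_equal(ss_conservation(x$a, ss, rule = "majority")$percent, 100)
})

test_that("Kabsch recovers exact congruence and planted transforms", {
  set.seed(7)
  P <- matrix(rnorm(30, sd = 4), ncol = 3)
  same <- kabsch_superpose(P, P)
  expect_lt(same$rmsd, 1e-10)
  expect_equal(same$R, diag(3), tolerance = 1e-8)
  R0 <- rot_xyz(0.3, 1.2, -0.7); t0 <- c(4, -2, 9)
  Q <- sweep(P %*% t(R0), 2, -t0)   # rotate P by R0 then translate
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-8)
  # recovered rotation inverts the planted one
  expect_lt(max(abs(fit$R - t(t(R0)))), 1e-6)
  fitted <- sweep(Q %*% fit$R, 2, fit$t, `+`)
  expect_lt(max(abs(fitted - P)), 1e-6)
})

test_that("Kabsch RMSD matches an independent optimizer and bio3d on noisy pairs", {
  set.seed(21)
  for (rep in 1:3) {
    P <- matrix(rnorm(30, sd = 3), ncol = 3)
    Q <- P %*% rot_xyz(runif(1), runif(1), runif(1)) +
      matrix(rnorm(30, sd = 0.5), ncol = 3)
    r_svd <- kabsch_superpose(P, Q)$rmsd
    expect_lt(abs(r_svd - rmsd_optim_oracle(P, Q)), 1e-3)
    r_bio3d <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
    expect_lt(abs(r_svd - r_bio3d), 1e-3)
  }
})

test_that("Kabsch RMSD is invariant to rigid pre-transforms of either input", {
  set.seed(3)
  P <- matrix(rnorm(24, sd = 3), ncol = 3)
  Q <- P + matrix(rnorm(24, sd = 0.4), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  P2 <- P %*% rot_xyz(1, 2, 3) + 5
  Q2 <- Q %*% rot_xyz(-2, 0.5, 1) - 3
  expect_equal(kabsch_superpose(P2, Q)$rmsd, base, tolerance = 1e-9)
  expect_equal(kabsch_superpose(P, Q2)$rmsd, base, tolerance = 1e-9)
})

test_that("Kabsch rejects tiny or mismatched inputs and flags collinear sets", {
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]),
               class = "psnalign_argument_error")
  line <- cbind(1:5, 0, 0)
  expect_warning(fit <- kabsch_superpose(line, line), "collinear")
  expect_true(fit$degenerate)
  expect_lt(fit$rmsd, 1e-10)
})

test_that("multi_superpose brings congruent members into one frame", {
  fx <- generate_fixture(fixture_spec(n_members = 4, base_length = 18,
                                      noise_sd = 0, seed = 14))
  sup <- multi_superpose(fx$structures, fx$alignment)
  expect_true(attr(sup, "converged"))
  cas <- lapply(sup, psnalign:::ca_coords)
  for (k in 2:4) expect_lt(max(abs(cas[[1]] - cas[[k]])), 1e-6)
})

test_that("member order does not change the post-superposition RMSD matrix", {
  fx <- generate_fixture(fixture_spec(n_members = 4, base_length = 18,
                                      noise_sd = 0.3, seed = 15))
  a <- fx$alignment
  M1 <- rmsd_matrix(fx$structures, a)
  perm <- c(3, 1, 4, 2)
  a2 <- psnalign:::build_alignment(a$ids[perm], a$ali[perm, ], fx$structures)
  M2 <- rmsd_matrix(fx$structures, a2)
  expect_equal(M1[a$ids, a$ids], M2[a$ids, a$ids], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("mean pairwise RMSD tracks the planted noise level", {
  # two congruent copies with iid N(0, sd) jitter on every coordinate: the
  # per-coordinate difference is N(0, 2 sd^2), so E[RMSD^2] = 6 sd^2 before
  # fitting; the rigid fit absorbs 6 of the 3n degrees of freedom
  sd <- 0.4; n <- 40
  expected <- sd * sqrt(6 * (3 * n - 6) / (3 * n))
  reps <- 20
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    fx <- generate_fixture(fixture_spec(n_members = 2, base_length = n,
                                        noise_sd = sd, seed = 100 + r))
    vals[r] <- rmsd_matrix(fx$structures, fx$alignment)[1, 2]
  }
  expect_lt(abs(mean(vals) - expected) / expected, 0.10)
})

test_that("rmsd_matrix is symmetric, zero-diagonal and matches pairwise Kabsch", {
  fx <- generate_fixture(fixture_spec(n_members = 3, base_length = 16,
                                      noise_sd = 0.5, seed = 33))
  a <- fx$alignment
  M <- rmsd_matrix(fx$structures, a)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(0, 3))
  expect_true(all(M >= 0))
  for (i in 1:2) for (j in (i + 1):3) {
    shared <- which(!is.na(a$col_map[[i]]) & !is.na(a$col_map[[j]]))
    Pi <- psnalign:::ca_coords(fx$structures[[a$ids[i]]])[a$col_map[[i]][shared], ]
    Pj <- psnalign:::ca_coords(fx$structures[[a$ids[j]]])[a$col_map[[j]][shared], ]
    expect_equal(M[i, j], kabsch_superpose(Pi, Pj)$rmsd, tolerance = 1e-12)
  }
})

test_that("identity matrix counts matches over co-occupied positions", {
  x <- make_alignment(list(m1 = "AC", m2 = "AG"))
  M <- identity_matrix(x$a)
  expect_equal(M["m1", "m2"], 50)
  y <- make_alignment(list(m1 = "ACDW", m2 = "ACDW"))
  expect_equal(identity_matrix(y$a)["m1", "m2"], 100)
  z <- make_alignment(list(m1 = "AC--", m2 = "A-D-", m3 = "ACDW"))
  Mz <- identity_matrix(z$a)
  expect_equal(Mz["m1", "m2"], 100)   # only column 1 co-occupied
  expect_equal(Mz, t(Mz))
})

test_that("UPGMA reproduces hand-computed trees and valid Newick", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma_tree(d2), "(A:1.5,B:1.5);")
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- upgma_tree(d3)
  phy <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(phy), 3)
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 8)
  expect_equal(coph["B", "C"], 8)
  # branch lengths from the hand computation: ((A:1,B:1):3,C:4)
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(unname(depths[1:3]), c(4, 4, 4))  # ultrametric leaves
})

test_that("UPGMA on an ultrametric input recovers the generating topology", {
  # planted tree: ((A,B),(C,D)) with within-pair distance 2, across 10
  ids <- c("A", "B", "C", "D")
  d <- matrix(10, 4, 4, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- 2; d[3, 4] <- d[4, 3] <- 2
  diag(d) <- 0
  phy <- ape::read.tree(text = upgma_tree(d))
  pairs <- ape::cophenetic.phylo(phy)
  expect_equal(pairs["A", "B"], 2)
  expect_equal(pairs["C", "D"], 2)
  expect_true(all(pairs[c("A", "B"), c("C", "D")] == 10))
  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2)),
               class = "psnalign_argument_error")
})
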