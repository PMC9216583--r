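# Shared helpers: tiny hand-built structures and independent oracles.

# A minimal domain_structure from explicit atom records.
# atoms: data.frame(res_index, name, x, y, z); resnames: 3-letter per residue
hand_structure <- function(domain_id, resnames, atoms, het = FALSE) {
  n <- length(resnames)
  residues <- data.frame(
    chain = "A", resno = seq_len(n), icode = "", resname = resnames,
    het = rep(het, length.out = n),
    aa = vapply(resnames, function(r) {
      a <- suppressWarnings(bio3d::aa321(r)); if (is.na(a)) "X" else a
    }, character(1)),
    stringsAsFactors = FALSE
  )
  atoms$occ <- 1
  structure(list(domain_id = domain_id, residues = residues,
                 atoms = atoms, cleaned = TRUE, removal_log = character(0)),
            class = "domain_structure")
}

# Structure with one CA (and optionally one CB) per residue at given coords.
ca_structure <- function(domain_id, ca, aa = NULL, cb = NULL) {
  n <- nrow(ca)
  if (is.null(aa)) aa <- rep("ALA", n)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      res_index = i, name = "N", x = ca[i, 1] + 0.4, y = ca[i, 2], z = ca[i, 3])
    rows[[length(rows) + 1L]] <- data.frame(
      res_index = i, name = "CA", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3])
    rows[[length(rows) + 1L]] <- data.frame(
      res_index = i, name = "C", x = ca[i, 1] - 0.4, y = ca[i, 2], z = ca[i, 3])
    rows[[length(rows) + 1L]] <- data.frame(
      res_index = i, name = "O", x = ca[i, 1], y = ca[i, 2] + 0.4, z = ca[i, 3])
    if (!is.null(cb) && !is.na(cb[i, 1])) {
      rows[[length(rows) + 1L]] <- data.frame(
        res_index = i, name = "CB", x = cb[i, 1], y = cb[i, 2], z = cb[i, 3])
    }
  }
  hand_structure(domain_id, aa, do.call(rbind, rows))
}

# Random-coordinate structure: CA in a box, one pseudo side-chain atom per
# non-glycine residue nearby. Exercises the network builders on irregular
# geometry.
random_structure <- function(n, seed, box = 18, domain_id = "rnd") {
  set.seed(seed)
  ca <- matrix(runif(3 * n, 0, box), ncol = 3)
  aa <- sample(c("ALA", "GLY", "LEU", "SER", "TRP"), n, replace = TRUE)
  cb <- ca + matrix(rnorm(3 * n, 0, 1.2), ncol = 3)
  cb[aa == "GLY", ] <- NA
  ca_structure(domain_id, ca, aa, cb)
}

# Independent proper rotation from three angles (used to plant transforms).
rot_xyz <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

edge_key_set <- function(e) paste(e[, 1], e[, 2], sep = ":")

# Brute-force superposition oracle: general-purpose optimizer over an
# axis-angle rotation (translation handled by centroid alignment), many
# restarts. Independent of the SVD route.
rmsd_optim_oracle <- function(P, Q, restarts = 25) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  obj <- function(par) {
    th <- sqrt(sum(par^2))
    R <- if (th < 1e-12) diag(3) else {
      k <- par / th
      K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    sqrt(mean(rowSums((Pc - Qc %*% R)^2)))
  }
  best <- Inf
  for (i in seq_len(restarts)) {
    r <- stats::optim(stats::rnorm(3, 0, 2), obj, method = "BFGS",
                      control = list(maxit = 500))
    best <- min(best, r$value)
  }
  best
}

# Rand index between two labelings (same member order).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# member_features object from a raw feature matrix (for clustering tests
# that do not need structures).
fake_features <- function(X, members = sprintf("m%d", seq_len(nrow(X)))) {
  f <- data.frame(member = members, gap_percent = X[, 1],
                  mean_rmsd = X[, 2], length = X[, 3],
                  stringsAsFactors = FALSE)
  sds <- apply(X, 2, stats::sd)
  z <- sweep(X, 2, colMeans(X))
  for (c in seq_len(ncol(z))) z[, c] <- if (sds[c] > 1e-9) z[, c] / sds[c] else 0
  attr(f, "z") <- z
  class(f) <- c("member_features", "data.frame")
  f
}
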