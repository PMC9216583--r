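#' Per-column conservation profile (ACR/HCR calls)
#'
#' A column is an absolutely conserved residue (ACR) when every member has
#' the identical residue there — full occupancy, no gaps. It is a highly
#' conserved residue (HCR) when the majority residue's fraction (majority
#' count / number of members, gaps counting as mismatches) falls in
#' `[hcr_low, 1)`; with the defaults that is the 80-99% conserved band.
#'
#' @param a a `struct_alignment`
#' @param acr required fraction for an ACR call, default 1.0
#' @param hcr_low lower bound of the HCR band, default 0.80
#' @return object of class `conservation_profile`: a per-column data frame
#'   (`column`, `occupancy`, `majority`, `fraction`, `class`) plus
#'   `acr_columns` and `hcr_columns`
#' @export
conservation_profile <- function(a, acr = 1.0, hcr_low = 0.80) {
  n <- length(a$ids)
  prof <- data.frame(column = seq_len(a$n_columns), occupancy = NA_real_,
                     majority = NA_character_, fraction = NA_real_,
                     class = ".", stringsAsFactors = FALSE)
  for (c in seq_len(a$n_columns)) {
    col <- a$ali[, c]
    res <- col[col != "-"]
    prof$occupancy[c] <- length(res) / n
    if (length(res) == 0L) { prof$fraction[c] <- 0; next }
    tab <- sort(table(res), decreasing = TRUE)
    # lexicographic tie-break for the reported majority residue
    top <- sort(names(tab)[tab == max(tab)])[1L]
    prof$majority[c] <- top
    prof$fraction[c] <- tab[[top]] / n
    if (prof$fraction[c] >= acr && prof$occupancy[c] == 1) {
      prof$class[c] <- "ACR"
    } else if (prof$fraction[c] >= hcr_low && prof$fraction[c] < acr) {
      prof$class[c] <- "HCR"
    }
  }
  structure(list(profile = prof,
                 acr_columns = prof$column[prof$class == "ACR"],
                 hcr_columns = prof$column[prof$class == "HCR"]),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns: %d ACR, %d HCR\n",
              nrow(x$profile), length(x$acr_columns), length(x$hcr_columns)))
  invisible(x)
}

#' Gap statistics of an alignment
#'
#' Per member, the percentage of gap characters in its row; plus the
#' superfamily mean over members.
#'
#' @param a a `struct_alignment`
#' @return object of class `gap_stats` with `per_member` (named numeric, %)
#'   and `mean` (%)
#' @export
gap_stats <- function(a) {
  per <- 100 * rowSums(a$ali == "-") / a$n_columns
  names(per) <- a$ids
  structure(list(per_member = per, mean = mean(per)), class = "gap_stats")
}

#' Secondary-structure conservation of an alignment
#'
#' Each member supplies one secondary-structure character (H/E/C) per
#' residue. A column's secondary structure is conserved when the column is
#' fully occupied and all members agree (`rule = "unanimous"`, the default)
#' or when a strict majority of members agree at a fully occupied column
#' (`rule = "majority"`).
#'
#' @param a a `struct_alignment`
#' @param ss named list or character vector of per-member SS strings, one
#'   character per (degapped) residue, alphabet H/E/C
#' @param rule "unanimous" (default) or "majority"
#' @return object of class `ss_conservation` with the per-column SS matrix
#'   (`'-'` at gaps), `conserved_columns` and `percent`
#' @export
ss_conservation <- function(a, ss, rule = c("unanimous", "majority")) {
  rule <- match.arg(rule)
  ss <- as.list(ss)
  m <- matrix("-", nrow = length(a$ids), ncol = a$n_columns,
              dimnames = list(a$ids, NULL))
  for (k in seq_along(a$ids)) {
    id <- a$ids[k]
    st <- ss[[id]]
    if (is.null(st)) {
      stop_psnalign("no secondary-structure string for member ", id,
                    class = "psnalign_consistency_error")
    }
    chars <- strsplit(st, "")[[1]]
    cm <- a$col_map[[k]]
    nres <- sum(!is.na(cm))
    if (length(chars) != nres) {
      stop_psnalign(sprintf(
        "member %s: SS string has %d characters but structure has %d residues",
        id, length(chars), nres), class = "psnalign_consistency_error")
    }
    m[k, !is.na(cm)] <- chars[cm[!is.na(cm)]]
  }
  full <- colSums(m != "-") == length(a$ids)
  agreed <- vapply(seq_len(a$n_columns), function(c) {
    if (!full[c]) return(FALSE)
    tab <- table(m[, c])
    if (rule == "unanimous") length(tab) == 1L
    else max(tab) > length(a$ids) / 2
  }, logical(1))
  structure(list(ss_columns = m,
                 conserved_columns = which(agreed),
                 percent = 100 * sum(agreed) / a$n_columns,
                 rule = rule),
            class = "ss_conservation")
}

#' Rigid-body (Kabsch) superposition of paired point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `P` and the transformed `Q` (rows are points): `Q %*% R + t`.
#' Uses the SVD of the cross-covariance with the determinant correction so
#' the result is always a proper rotation (det +1), never a reflection.
#'
#' @param P n x 3 reference coordinates
#' @param Q n x 3 coordinates to fit, paired row-wise with P
#' @return list with `R` (3x3 rotation), `t` (length-3 translation),
#'   `rmsd` (Angstrom) and `degenerate` (TRUE when the point set is
#'   near-collinear and the rotation is not uniquely determined)
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L) {
    stop_psnalign("P and Q must be paired n x 3 matrices",
                  class = "psnalign_argument_error")
  }
  if (nrow(P) < 3L) {
    stop_psnalign("need at least 3 paired points",
                  class = "psnalign_argument_error")
  }
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(Q0, P0)           # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  degenerate <- sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)
  if (degenerate) {
    warning("near-degenerate (collinear) point set; rotation not unique")
  }
  fitted <- Q0 %*% R
  rmsd <- sqrt(mean(rowSums((P0 - fitted)^2)))
  t <- as.numeric(pc - qc %*% R)
  list(R = R, t = t, rmsd = rmsd, degenerate = degenerate)
}

# CA coordinates of member k restricted to the given alignment columns
# (which must be non-gap for that member).
member_ca_at <- function(s, cm, cols) {
  ca_coords(s)[cm[cols], , drop = FALSE]
}

apply_rigid <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1L] + t[1L]
  s$atoms$y <- xyz[, 2L] + t[2L]
  s$atoms$z <- xyz[, 3L] + t[3L]
  s
}

#' Iterative multiple superposition onto a consensus frame
#'
#' All members are superposed into one common frame by iterating: compute
#' the mean C-alpha coordinates over fully occupied alignment columns,
#' superpose every member onto that mean, recompute. Stops when the mean
#' moves less than `tol` (RMS, Angstrom) or after `max_iter` iterations.
#'
#' @param structures named list of cleaned `domain_structure` objects
#' @param a the `struct_alignment` over those members
#' @param tol convergence tolerance on the consensus coordinates, default 1e-4
#' @param max_iter default 100
#' @return named list of `domain_structure` objects with transformed
#'   coordinates, with attributes `iterations` and `converged`
#' @export
multi_superpose <- function(structures, a, tol = 1e-4, max_iter = 100L) {
  ids <- a$ids
  if (length(ids) < 2L) {
    stop_psnalign("need at least 2 members", class = "psnalign_argument_error")
  }
  occ <- Reduce(`+`, lapply(a$col_map, function(cm) !is.na(cm)))
  cols <- which(occ == length(ids))
  if (length(cols) < 3L) {
    stop_psnalign("fewer than 3 fully occupied columns: cannot superpose",
                  class = "psnalign_argument_error")
  }
  out <- structures[ids]
  # initialize onto the first member's frame
  ref <- member_ca_at(out[[1L]], a$col_map[[1L]], cols)
  for (k in seq_along(ids)[-1L]) {
    fit <- kabsch_superpose(ref, member_ca_at(out[[k]], a$col_map[[k]], cols))
    out[[k]] <- apply_rigid(out[[k]], fit$R, fit$t)
  }
  consensus <- ref
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (k in seq_along(ids)) {
      fit <- kabsch_superpose(consensus,
                              member_ca_at(out[[k]], a$col_map[[k]], cols))
      out[[k]] <- apply_rigid(out[[k]], fit$R, fit$t)
    }
    new_consensus <- Reduce(`+`, lapply(seq_along(ids), function(k) {
      member_ca_at(out[[k]], a$col_map[[k]], cols)
    })) / length(ids)
    shift <- sqrt(mean(rowSums((new_consensus - consensus)^2)))
    consensus <- new_consensus
    if (shift < tol) { converged <- TRUE; break }
  }
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Pairwise C-alpha RMSD matrix
#'
#' Entry (i, j) is the RMSD after pair-specific Kabsch superposition over
#' the columns where both members are non-gap. Pairs sharing fewer than 3
#' columns are flagged missing (NA).
#'
#' @param structures named list of cleaned `domain_structure` objects
#' @param a the `struct_alignment`
#' @return symmetric matrix (Angstrom) with zero diagonal and member-id
#'   dimnames; attribute `mean_rmsd` holds the mean of the off-diagonal
#'   upper triangle (NA entries excluded)
#' @export
rmsd_matrix <- function(structures, a) {
  ids <- a$ids
  n <- length(ids)
  if (n < 2L) {
    stop_psnalign("need at least 2 members", class = "psnalign_argument_error")
  }
  cas <- lapply(seq_len(n), function(k) ca_coords(structures[[ids[k]]]))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- which(!is.na(a$col_map[[i]]) & !is.na(a$col_map[[j]]))
      if (length(shared) < 3L) {
        M[i, j] <- M[j, i] <- NA_real_
        next
      }
      fit <- kabsch_superpose(cas[[i]][a$col_map[[i]][shared], , drop = FALSE],
                              cas[[j]][a$col_map[[j]][shared], , drop = FALSE])
      M[i, j] <- M[j, i] <- fit$rmsd
    }
  }
  ut <- M[upper.tri(M)]
  attr(M, "mean_rmsd") <- mean(ut, na.rm = TRUE)
  M
}

#' Pairwise sequence identity matrix
#'
#' Entry (i, j) is 100 x (identical positions) / (positions where both
#' members are non-gap). Pairs with no co-occupied column are NA. The
#' diagonal is 100.
#'
#' @param a a `struct_alignment`
#' @return symmetric percentage matrix with member-id dimnames
#' @export
identity_matrix <- function(a) {
  ids <- a$ids
  n <- length(ids)
  if (n < 2L) {
    stop_psnalign("need at least 2 members", class = "psnalign_argument_error")
  }
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- a$ali[i, ] != "-" & a$ali[j, ] != "-"
      M[i, j] <- M[j, i] <- if (!any(both)) NA_real_ else {
        100 * sum(a$ali[i, both] == a$ali[j, both]) / sum(both)
      }
    }
  }
  M
}

#' UPGMA structural dissimilarity tree
#'
#' Average-linkage agglomeration of a complete symmetric distance matrix
#' with ultrametric branch lengths (leaf depth = merge height / 2).
#' Ties are broken deterministically by sorting members lexicographically
#' before clustering.
#'
#' @param d complete symmetric non-negative distance matrix with dimnames
#' @return Newick string (with trailing semicolon)
#' @export
upgma_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) {
    stop_psnalign("distance matrix has missing entries",
                  class = "psnalign_argument_error")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("m", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  if (nrow(d) == 2L) {
    # hclust needs >= 2 merges; handle the 2-leaf case directly
    return(sprintf("(%s:%g,%s:%g);", rownames(d)[1L], d[1, 2] / 2,
                   rownames(d)[2L], d[1, 2] / 2))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)   # divides merge heights by 2 -> ultrametric
  ape::write.tree(phy)
}

#' Structural dissimilarity summary for a superfamily
#'
#' Convenience wrapper assembling the pairwise RMSD matrix, its mean, the
#' sequence identity matrix and the UPGMA tree.
#'
#' @inheritParams rmsd_matrix
#' @return object of class `struct_dissimilarity` with `rmsd`, `mean_rmsd`,
#'   `identity` and `tree` (Newick; NULL when the RMSD matrix is incomplete)
#' @export
struct_dissimilarity <- function(structures, a) {
  M <- rmsd_matrix(structures, a)
  tree <- if (anyNA(M)) NULL else upgma_tree(M)
  structure(list(rmsd = M, mean_rmsd = attr(M, "mean_rmsd"),
                 identity = identity_matrix(a), tree = tree),
            class = "struct_dissimilarity")
}

#' @export
print.struct_dissimilarity <- function(x, ...) {
  cat(sprintf("<struct_dissimilarity> %d members, mean CA RMSD %.3f A\n",
              nrow(x$rmsd), x$mean_rmsd))
  invisible(x)
}

#' Write a labelled matrix as TSV
#' @param M matrix with dimnames
#' @param path output path
#' @export
write_matrix_tsv <- function(M, path) {
  utils::write.table(format(M, digits = 6, trim = TRUE), file = path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
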