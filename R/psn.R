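#' PSN construction parameters
#'
#' Cutoffs for the two network levels. Backbone contacts are defined on
#' C-alpha atoms within 7.5 Angstrom; side-chain contacts on any pair of
#' side-chain atoms (all atoms except N, CA, C, O; OXT counts as backbone)
#' within 4.5 Angstrom. Both comparisons are inclusive (distance <= cutoff).
#' `min_seq_separation` is the minimum |i - j| between residue indices for a
#' pair to be eligible; the default 1 allows sequence-adjacent contacts.
#'
#' @param backbone_cutoff Angstrom, default 7.5
#' @param sidechain_cutoff Angstrom, default 4.5
#' @param min_seq_separation integer >= 1, default 1
#' @return a list of class `psn_config`
#' @export
psn_config <- function(backbone_cutoff = 7.5, sidechain_cutoff = 4.5,
                       min_seq_separation = 1L) {
  stopifnot(backbone_cutoff > 0, sidechain_cutoff > 0,
            min_seq_separation >= 1)
  structure(list(backbone_cutoff = backbone_cutoff,
                 sidechain_cutoff = sidechain_cutoff,
                 min_seq_separation = as.integer(min_seq_separation)),
            class = "psn_config")
}

# Atom names excluded from the side-chain atom set.
.MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

ca_coords <- function(s) {
  idx <- which(s$atoms$name == "CA")
  idx <- idx[!duplicated(s$atoms$res_index[idx])]
  if (length(idx) != nrow(s$residues)) {
    stop_psnalign("structure ", s$domain_id,
                  " has residues without CA atoms; clean it first",
                  class = "psnalign_precondition_error")
  }
  m <- as.matrix(s$atoms[idx, c("x", "y", "z")])[order(s$atoms$res_index[idx]), ,
                                                 drop = FALSE]
  rownames(m) <- NULL
  m
}

new_psn <- function(domain_id, level, n_nodes, edges, dist) {
  structure(list(domain_id = domain_id, level = level,
                 n_nodes = as.integer(n_nodes),
                 edges = edges, dist = dist),
            class = "psn")
}

#' Build the backbone protein structure network
#'
#' Residues are nodes; an edge joins residues i and j when their C-alpha
#' atoms are within `backbone_cutoff` (inclusive) and |i - j| >=
#' `min_seq_separation`.
#'
#' @param s a cleaned `domain_structure`
#' @param cfg a [psn_config()]
#' @return an object of class `psn` with fields `domain_id`, `level`,
#'   `n_nodes`, `edges` (two-column matrix of residue index pairs, i < j)
#'   and `dist` (contact distances, Angstrom)
#' @export
build_backbone_psn <- function(s, cfg = psn_config()) {
  ca <- ca_coords(s)
  n <- nrow(ca)
  if (n == 1L) {
    return(new_psn(s$domain_id, "backbone", n, canonical_edges(NULL), numeric(0)))
  }
  D <- as.matrix(stats::dist(ca))
  sep <- abs(row(D) - col(D))
  hit <- which(upper.tri(D) & D <= cfg$backbone_cutoff &
                 sep >= cfg$min_seq_separation, arr.ind = TRUE)
  e <- canonical_edges(hit)
  new_psn(s$domain_id, "backbone", n, e, D[e])
}

#' Build the side-chain protein structure network
#'
#' An edge joins residues i and j when any side-chain atom of i is within
#' `sidechain_cutoff` (inclusive) of any side-chain atom of j and |i - j| >=
#' `min_seq_separation`. Side-chain atoms are all atoms except N, CA, C, O
#' (and OXT). Residues without side-chain atoms (glycine) are isolated nodes.
#'
#' @inheritParams build_backbone_psn
#' @return a `psn`; `dist` holds the minimum atom-pair distance per edge
#' @export
build_sidechain_psn <- function(s, cfg = psn_config()) {
  n <- nrow(s$residues)
  sc <- s$atoms[!(s$atoms$name %in% .MAINCHAIN_ATOMS), , drop = FALSE]
  if (nrow(sc) < 2L) {
    return(new_psn(s$domain_id, "sidechain", n, canonical_edges(NULL), numeric(0)))
  }
  D <- as.matrix(stats::dist(as.matrix(sc[, c("x", "y", "z")])))
  ri <- sc$res_index
  hit <- which(upper.tri(D) & D <= cfg$sidechain_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(new_psn(s$domain_id, "sidechain", n, canonical_edges(NULL), numeric(0)))
  }
  a <- ri[hit[, 1L]]; b <- ri[hit[, 2L]]
  d <- D[hit]
  ok <- abs(a - b) >= cfg$min_seq_separation
  a <- a[ok]; b <- b[ok]; d <- d[ok]
  if (length(a) == 0L) {
    return(new_psn(s$domain_id, "sidechain", n, canonical_edges(NULL), numeric(0)))
  }
  i <- pmin(a, b); j <- pmax(a, b)
  key <- paste(i, j, sep = ":")
  dmin <- tapply(d, key, min)
  e <- canonical_edges(cbind(i, j))
  new_psn(s$domain_id, "sidechain", n, e, as.numeric(dmin[edge_keys(e)]))
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("<psn> %s [%s]: %d nodes, %d edges\n",
              x$domain_id, x$level, x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Write a PSN as a tab-separated edge list
#'
#' One line per edge: level, residue key i, residue key j, distance (3
#' decimals), in lexicographic order of the residue index pair.
#'
#' @param p a `psn`
#' @param s the `domain_structure` the network was built from (for residue
#'   keys)
#' @param path output path
#' @export
write_psn_edges <- function(p, s, path) {
  e <- p$edges
  lines <- if (nrow(e)) {
    sprintf("%s\t%s\t%s\t%.3f", p$level,
            res_key(s, e[, 1L]), res_key(s, e[, 2L]), p$dist)
  } else character(0)
  writeLines(c("# level\tres_i\tres_j\tdistance", lines), path)
  invisible(path)
}
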