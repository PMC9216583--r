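# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonicalize an edge matrix
#'
#' Orders each row so the smaller index comes first, drops duplicates and
#' sorts rows lexicographically. Used everywhere an edge set is compared or
#' written, so that edge sets have a single representation.
#'
#' @param e two-column integer matrix of index pairs (possibly 0 rows)
#' @return two-column integer matrix, i < j, unique, sorted by (i, j)
#' @keywords internal
#' @noRd
canonical_edges <- function(e) {
  if (is.null(e) || length(e) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  e <- matrix(as.integer(e), ncol = 2L)
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, c(2L, 1L), drop = FALSE]
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("i", "j"))
  e
}

edge_keys <- function(e) {
  if (nrow(e) == 0L) return(character(0))
  paste(e[, 1L], e[, 2L], sep = ":")
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# "chain:resno:icode:resname" label for residue row i of a structure.
res_key <- function(s, i) {
  r <- s$residues[i, , drop = FALSE]
  sprintf("%s:%d:%s:%s", r$chain, r$resno, ifelse(r$icode == "", ".", r$icode),
          r$resname)
}

stop_psnalign <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "psnalign_error")))
}
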