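#' Project a member's PSN onto alignment columns
#'
#' Gap positions become dummy nodes (NA); every PSN edge maps to exactly one
#' column pair, so the number of column edges equals the number of PSN edges.
#'
#' @param p a `psn` for one member
#' @param a the `struct_alignment` containing that member
#' @return an object of class `aligned_network` with `column_nodes` (integer
#'   vector over columns; residue index or NA for a dummy node) and
#'   `column_edges` (two-column matrix of column pairs)
#' @export
align_network <- function(p, a) {
  k <- match(p$domain_id, a$ids)
  if (is.na(k)) {
    stop_psnalign("domain ", p$domain_id, " is not an alignment member",
                  class = "psnalign_lookup_error")
  }
  cm <- a$col_map[[k]]
  col_of <- rep(NA_integer_, p$n_nodes)
  col_of[cm[!is.na(cm)]] <- which(!is.na(cm))
  ce <- canonical_edges(cbind(col_of[p$edges[, 1L]], col_of[p$edges[, 2L]]))
  structure(
    list(domain_id = p$domain_id, level = p$level, n_columns = a$n_columns,
         column_nodes = cm, column_edges = ce),
    class = "aligned_network"
  )
}

new_aci_set <- function(level, n_columns, edges, support) {
  structure(list(level = level, n_columns = n_columns,
                 edges = edges, support = support),
            class = "aci_set")
}

#' Absolutely conserved interactions across a superfamily
#'
#' An interaction (edge) is absolutely conserved when the same column pair
#' carries an edge in every member's aligned network: the strict intersection
#' of the members' column edge sets. A gap (dummy node) in any member at
#' either column therefore breaks conservation. `min_support` relaxes the
#' rule to a fraction of members (1 = all, the default and the standard
#' definition).
#'
#' @param nets non-empty list of `aligned_network` objects sharing one
#'   alignment and one level
#' @param level optional; checked against the networks if given
#' @param min_support fraction of members required to carry the edge,
#'   default 1 (absolute conservation)
#' @return an object of class `aci_set`; `support` maps each member to the
#'   realized residue-index pair per conserved edge (NA rows where a member
#'   below full support lacks the edge)
#' @export
find_acis <- function(nets, level = NULL, min_support = 1) {
  if (length(nets) == 0L) {
    stop_psnalign("empty network list", class = "psnalign_argument_error")
  }
  levels <- unique(vapply(nets, `[[`, character(1), "level"))
  if (length(levels) != 1L || (!is.null(level) && levels != level)) {
    stop_psnalign("networks have mixed or unexpected levels: ",
                  paste(levels, collapse = ", "),
                  class = "psnalign_argument_error")
  }
  ncols <- unique(vapply(nets, `[[`, integer(1), "n_columns"))
  if (length(ncols) != 1L) {
    stop_psnalign("networks built on different alignments",
                  class = "psnalign_argument_error")
  }
  keysets <- lapply(nets, function(nw) edge_keys(nw$column_edges))
  all_keys <- unique(unlist(keysets))
  counts <- as.integer(table(factor(unlist(keysets), levels = all_keys)))
  need <- max(1, ceiling(min_support * length(nets)))
  kept <- all_keys[counts >= need]
  edges <- if (length(kept)) {
    canonical_edges(do.call(rbind, lapply(strsplit(kept, ":"), as.integer)))
  } else canonical_edges(NULL)

  support <- lapply(nets, function(nw) {
    cm <- nw$column_nodes
    cbind(i = cm[edges[, 1L]], j = cm[edges[, 2L]])
  })
  names(support) <- vapply(nets, `[[`, character(1), "domain_id")
  new_aci_set(levels, ncols, edges, support)
}

#' Interactions conserved at both network levels
#'
#' @param bb backbone-level `aci_set`
#' @param sc sidechain-level `aci_set` on the same alignment
#' @return an `aci_set` with level "common": the column-pair intersection
#' @export
common_acis <- function(bb, sc) {
  stopifnot(inherits(bb, "aci_set"), inherits(sc, "aci_set"))
  if (bb$n_columns != sc$n_columns) {
    stop_psnalign("ACI sets from different alignments",
                  class = "psnalign_argument_error")
  }
  keep <- edge_keys(bb$edges) %in% edge_keys(sc$edges)
  edges <- canonical_edges(bb$edges[keep, , drop = FALSE])
  support <- lapply(bb$support, function(m) m[keep, , drop = FALSE])
  new_aci_set("common", bb$n_columns, edges, support)
}

#' @export
print.aci_set <- function(x, ...) {
  cat(sprintf("<aci_set> level %s: %d conserved interactions over %d members\n",
              x$level, nrow(x$edges), length(x$support)))
  invisible(x)
}

#' Write an ACI report as TSV
#'
#' Columns: level, col_i, col_j, then one column per member holding the
#' realized residue pair as "chain:resno:icode:resname-chain:resno:icode:resname".
#'
#' @param acis an `aci_set`
#' @param structures named list of `domain_structure` objects covering every
#'   supporting member
#' @param path output path
#' @export
aci_report <- function(acis, structures, path) {
  ids <- names(acis$support)
  header <- paste(c("level", "col_i", "col_j", ids), collapse = "\t")
  n <- nrow(acis$edges)
  lines <- character(n)
  for (r in seq_len(n)) {
    cells <- vapply(ids, function(id) {
      pr <- acis$support[[id]][r, ]
      if (anyNA(pr)) return(".")
      paste(res_key(structures[[id]], pr[1L]),
            res_key(structures[[id]], pr[2L]), sep = "-")
    }, character(1))
    lines[r] <- paste(c(acis$level, acis$edges[r, 1L], acis$edges[r, 2L], cells),
                      collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Emit a PyMOL command script drawing the conserved interactions
#'
#' The script loads one object per member (expected as `<domain_id>.pdb`
#' next to the script) and draws one distance object per ACI per member
#' between the C-alpha atoms of the two endpoint residues, colored by level.
#' Output is deterministic: regenerating it yields a byte-identical file.
#'
#' @param structures named list of superposed `domain_structure` objects
#' @param acis an `aci_set`
#' @param path output path for the .pml script
#' @export
write_pml <- function(structures, acis, path) {
  level_col <- c(backbone = "marine", sidechain = "orange", common = "red")
  col <- level_col[[acis$level]] %||% "yellow"
  ids <- names(acis$support)
  lines <- c(
    "# conserved-interaction visualization script",
    "bg_color white",
    "set dash_gap, 0.2",
    sprintf("load %s.pdb, %s", ids, ids),
    "hide everything",
    "show cartoon",
    "color grey80"
  )
  for (r in seq_len(nrow(acis$edges))) {
    for (id in ids) {
      pr <- acis$support[[id]][r, ]
      stopifnot(!anyNA(pr))  # guaranteed by absolute conservation
      s <- structures[[id]]
      sel <- function(i) {
        res <- s$residues[i, ]
        sprintf("/%s//%s/%d%s/CA", id,
                ifelse(res$chain == "", "A", res$chain), res$resno, res$icode)
      }
      nm <- sprintf("aci_%s_%d_%d_%s", acis$level,
                    acis$edges[r, 1L], acis$edges[r, 2L], id)
      lines <- c(lines,
                 sprintf("distance %s, %s, %s", nm, sel(pr[1L]), sel(pr[2L])),
                 sprintf("color %s, %s", col, nm))
    }
  }
  lines <- c(lines, "set dash_radius, 0.08", "zoom")
  writeLines(lines, path)
  invisible(path)
}
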