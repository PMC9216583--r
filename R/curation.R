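#' Curation configuration
#'
#' Thresholds for the alignment-improvement procedure. A superfamily is
#' flagged when it has at least `min_members` members, at least one member
#' contributes more than `flag_gap_percent` gaps to its alignment row, and
#' the conserved secondary-structure content is below `flag_ss_percent`.
#' The default SS threshold is 30%; 40% is a documented alternative.
#' Dwarf/giant members are singleton-cluster members shorter than
#' `dwarf_len_factor` x median length / longer than `giant_len_factor` x
#' median length; structural outliers exceed `structural_rmsd_cutoff` in
#' mean CA RMSD to the other members.
#'
#' @param flag_gap_percent default 50
#' @param flag_ss_percent default 30
#' @param min_members default 5
#' @param kmax maximum k for the elbow scan; default min(6, n_members - 1)
#' @param dwarf_len_factor default 0.5
#' @param giant_len_factor default 1.5
#' @param structural_rmsd_cutoff Angstrom, default 10
#' @param trim_occupancy a giant's residue is trimmed when its column is
#'   occupied by at most this many members, default 1 (private columns)
#' @param seed RNG seed for clustering, default 1
#' @return list of class `curation_config`
#' @export
curation_config <- function(flag_gap_percent = 50, flag_ss_percent = 30,
                            min_members = 5, kmax = NULL,
                            dwarf_len_factor = 0.5, giant_len_factor = 1.5,
                            structural_rmsd_cutoff = 10,
                            trim_occupancy = 1, seed = 1L) {
  stopifnot(flag_gap_percent > 0, flag_gap_percent < 100,
            flag_ss_percent > 0, flag_ss_percent < 100,
            dwarf_len_factor > 0, giant_len_factor > 0,
            structural_rmsd_cutoff > 0, trim_occupancy >= 1)
  structure(list(flag_gap_percent = flag_gap_percent,
                 flag_ss_percent = flag_ss_percent,
                 min_members = as.integer(min_members),
                 kmax = if (is.null(kmax)) NULL else as.integer(kmax),
                 dwarf_len_factor = dwarf_len_factor,
                 giant_len_factor = giant_len_factor,
                 structural_rmsd_cutoff = structural_rmsd_cutoff,
                 trim_occupancy = as.integer(trim_occupancy),
                 seed = as.integer(seed)),
            class = "curation_config")
}

#' Flag a superfamily for curation
#'
#' @param gaps a [gap_stats()] result
#' @param ssc an [ss_conservation()] result
#' @param cfg a [curation_config()]
#' @return TRUE when the superfamily qualifies for the improvement procedure
#' @export
flag_superfamily <- function(gaps, ssc, cfg = curation_config()) {
  length(gaps$per_member) >= cfg$min_members &&
    max(gaps$per_member) > cfg$flag_gap_percent &&
    ssc$percent < cfg$flag_ss_percent
}

#' Per-member clustering features
#'
#' The three features driving curation: percentage of gaps in the member's
#' row, mean CA RMSD to the other members (row mean of the RMSD matrix,
#' diagonal excluded) and domain length in residues. A z-scored copy (used
#' for clustering; columns with zero variance become zeros) is attached as
#' attribute `z`.
#'
#' @param a a `struct_alignment`
#' @param structures named list of `domain_structure` objects
#' @param rmsd pairwise RMSD matrix from [rmsd_matrix()] (no missing entries)
#' @return data frame of class `member_features` with columns `member`,
#'   `gap_percent`, `mean_rmsd`, `length`
#' @export
extract_features <- function(a, structures, rmsd) {
  if (anyNA(rmsd)) {
    stop_psnalign("RMSD matrix has missing entries",
                  class = "psnalign_argument_error")
  }
  g <- gap_stats(a)
  n <- length(a$ids)
  mean_rmsd <- vapply(seq_len(n), function(i) mean(rmsd[i, -i]), numeric(1))
  f <- data.frame(member = a$ids,
                  gap_percent = as.numeric(g$per_member[a$ids]),
                  mean_rmsd = mean_rmsd,
                  length = vapply(a$ids, function(id)
                    nrow(structures[[id]]$residues), integer(1)),
                  stringsAsFactors = FALSE)
  rownames(f) <- NULL
  X <- as.matrix(f[, c("gap_percent", "mean_rmsd", "length")])
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  z <- sweep(X, 2, mu)
  for (c in seq_len(ncol(z))) {
    # a feature with (numerically) no spread carries no signal: zero it
    # rather than dividing by a machine-noise sd
    z[, c] <- if (sds[c] > 1e-9) z[, c] / sds[c] else 0
  }
  attr(f, "z") <- z
  class(f) <- c("member_features", "data.frame")
  f
}

#' k-means clustering with elbow-based model selection
#'
#' Runs Lloyd k-means (25 random restarts, fixed seed) on the z-scored
#' features for k = 1..kmax and picks the elbow: the k whose point
#' (k, inertia_k) lies farthest (perpendicular distance) from the chord
#' joining (1, inertia_1) and (kmax, inertia_kmax). Deterministic for a
#' fixed `cfg$seed`. When inertia is already 0 at k = 1 (all members
#' identical) the chosen k is 1.
#'
#' @param f a [extract_features()] result
#' @param cfg a [curation_config()]
#' @return object of class `cluster_result`: `inertia_by_k` (named numeric),
#'   `chosen_k`, `labels` (named integer vector over members)
#' @export
kmeans_elbow <- function(f, cfg = curation_config()) {
  z <- attr(f, "z")
  n <- nrow(z)
  if (n < 2L) {
    stop_psnalign("need at least 2 members to cluster",
                  class = "psnalign_argument_error")
  }
  kmax <- max(1L, cfg$kmax %||% min(6L, n - 1L))
  n_distinct <- nrow(unique(z))
  fits <- with_seed(cfg$seed, {
    lapply(seq_len(kmax), function(k) {
      if (k == 1L) {
        list(tot.withinss = sum(sweep(z, 2, colMeans(z))^2),
             cluster = rep(1L, n))
      } else if (k >= n_distinct) {
        # each distinct point is its own center: zero inertia
        list(tot.withinss = 0,
             cluster = as.integer(factor(apply(z, 1, paste, collapse = "\r"))))
      } else {
        suppressWarnings(stats::kmeans(z, centers = k, nstart = 25L,
                                       iter.max = 100L, algorithm = "Lloyd"))
      }
    })
  })
  inertia <- vapply(fits, function(x) x$tot.withinss, numeric(1))
  names(inertia) <- seq_len(kmax)
  chosen_k <- elbow_k(inertia)
  labels <- fits[[chosen_k]]$cluster
  names(labels) <- f$member
  structure(list(inertia_by_k = inertia, chosen_k = chosen_k,
                 labels = labels, kmax = kmax),
            class = "cluster_result")
}

# Max perpendicular distance from (k, inertia_k) to the chord joining the
# first and last points of the inertia curve.
elbow_k <- function(inertia) {
  K <- length(inertia)
  if (K == 1L || inertia[1L] <= .Machine$double.eps) return(1L)
  # scale axes so k and inertia are commensurate before measuring distance
  x <- (seq_len(K) - 1) / max(K - 1, 1)
  y <- inertia / inertia[1L]
  v <- c(x[K] - x[1L], y[K] - y[1L])
  v <- v / sqrt(sum(v^2))
  d <- vapply(seq_len(K), function(i) {
    w <- c(x[i] - x[1L], y[i] - y[1L])
    abs(w[1L] * v[2L] - w[2L] * v[1L])
  }, numeric(1))
  as.integer(which.max(d))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k = %d (of 1..%d)\n", x$chosen_k, x$kmax))
  print(x$labels)
  invisible(x)
}

new_action <- function(kind, targets, rationale, partition = NULL) {
  structure(list(kind = kind, targets = targets, rationale = rationale,
                 partition = partition),
            class = "curation_action")
}

#' @export
print.curation_action <- function(x, ...) {
  cat(sprintf("<curation_action> %s [%s]: %s\n", x$kind,
              paste(x$targets, collapse = ", "), x$rationale))
  invisible(x)
}

#' Classify outlier members and recommend curation actions
#'
#' Rules, in order: (1) each singleton cluster's member is classified as a
#' giant (length > giant factor x median), else a dwarf (length < dwarf
#' factor x median), else a structural outlier (mean RMSD to others above
#' the cutoff), else left alone; (2) if at least two clusters with two or
#' more members remain, the superfamily is split along those clusters;
#' (3) otherwise no action.
#'
#' @param f a [extract_features()] result
#' @param cl a [kmeans_elbow()] result
#' @param cfg a [curation_config()]
#' @return list of `curation_action` objects (a single `none` action when
#'   nothing is recommended)
#' @export
classify_outliers <- function(f, cl, cfg = curation_config()) {
  labels <- cl$labels
  sizes <- table(labels)
  med_len <- stats::median(f$length)
  actions <- list()
  removed <- character(0)
  for (lab in sort(as.integer(names(sizes)[sizes == 1L]))) {
    member <- names(labels)[labels == lab]
    row <- f[f$member == member, ]
    if (row$length > cfg$giant_len_factor * med_len) {
      actions <- c(actions, list(new_action(
        "trim_giant", member,
        sprintf("singleton cluster; length %d > %.1f x median %.1f",
                row$length, cfg$giant_len_factor, med_len))))
    } else if (row$length < cfg$dwarf_len_factor * med_len) {
      actions <- c(actions, list(new_action(
        "remove_dwarf", member,
        sprintf("singleton cluster; length %d < %.1f x median %.1f",
                row$length, cfg$dwarf_len_factor, med_len))))
      removed <- c(removed, member)
    } else if (row$mean_rmsd > cfg$structural_rmsd_cutoff) {
      actions <- c(actions, list(new_action(
        "remove_structural_outlier", member,
        sprintf("singleton cluster; mean CA RMSD %.1f A > %.1f A",
                row$mean_rmsd, cfg$structural_rmsd_cutoff))))
      removed <- c(removed, member)
    }
  }
  multi <- names(sizes)[sizes >= 2L]
  if (length(multi) >= 2L) {
    part <- labels[labels %in% as.integer(multi)]
    actions <- c(actions, list(new_action(
      "split", names(part),
      sprintf("%d clusters with >= 2 members remain", length(multi)),
      partition = part)))
  }
  if (length(actions) == 0L) {
    actions <- list(new_action("none", character(0), "single coherent cluster"))
  }
  actions
}

#' Trim a giant member's private overhang
#'
#' Removes the member's residues in columns occupied by at most
#' `cfg$trim_occupancy` members (with the default 1: columns where the
#' giant is the only non-gap member), then drops the resulting all-gap
#' columns. Structure and alignment stay mutually consistent; original
#' residue numbering is preserved in the trimmed structure.
#'
#' @param s the giant member's `domain_structure`
#' @param a the `struct_alignment`
#' @param member the giant's id
#' @param cfg a [curation_config()]
#' @param structures named list of all members' structures (for
#'   re-validation)
#' @return list with the trimmed `structure`, the edited `alignment` and
#'   `trimmed_columns`
#' @export
trim_giant <- function(s, a, member, cfg = curation_config(),
                       structures = NULL) {
  k <- match(member, a$ids)
  if (is.na(k)) {
    stop_psnalign("member ", member, " not in alignment",
                  class = "psnalign_lookup_error")
  }
  occ <- colSums(a$ali != "-")
  private <- which(a$ali[k, ] != "-" & occ <= cfg$trim_occupancy)
  if (length(private) == 0L) {
    return(list(structure = s, alignment = a, trimmed_columns = integer(0)))
  }
  drop_res <- a$col_map[[k]][private]
  keep_res <- setdiff(seq_len(nrow(s$residues)), drop_res)
  if (length(keep_res) < 3L) {
    stop_psnalign("trimming would leave fewer than 3 residues",
                  class = "psnalign_argument_error")
  }
  new_index <- match(s$atoms$res_index, keep_res)
  atoms <- s$atoms[!is.na(new_index), , drop = FALSE]
  atoms$res_index <- new_index[!is.na(new_index)]
  rownames(atoms) <- NULL
  res <- s$residues[keep_res, , drop = FALSE]
  rownames(res) <- NULL
  s2 <- structure(
    list(domain_id = s$domain_id, residues = res, atoms = atoms,
         cleaned = s$cleaned,
         removal_log = c(s$removal_log,
                         sprintf("trimmed %d private-column residues",
                                 length(drop_res)))),
    class = "domain_structure")

  ali <- a$ali
  ali[k, private] <- "-"
  keep_cols <- which(colSums(ali != "-") > 0L)
  ali <- ali[, keep_cols, drop = FALSE]
  sts <- structures
  if (is.null(sts)) sts <- stats::setNames(list(s2), member)
  sts[[member]] <- s2
  # other members' structures are unchanged; rebuild maps from the rows
  a2 <- build_alignment(a$ids, ali, sts)
  list(structure = s2, alignment = a2, trimmed_columns = private,
       kept_residues = keep_res)
}

#' Remove a member from an alignment
#'
#' Drops the member's row and any column left all-gap. Warns when fewer
#' than two members remain (the product is then a single-member record).
#'
#' @param a a `struct_alignment`
#' @param member member id to remove
#' @param structures named list of structures for the remaining members
#' @return the edited `struct_alignment`
#' @export
remove_member <- function(a, member, structures) {
  k <- match(member, a$ids)
  if (is.na(k)) {
    stop_psnalign("member ", member, " not in alignment",
                  class = "psnalign_lookup_error")
  }
  ids <- a$ids[-k]
  if (length(ids) == 0L) {
    stop_psnalign("cannot remove the last member",
                  class = "psnalign_argument_error")
  }
  ali <- a$ali[-k, , drop = FALSE]
  ali <- ali[, colSums(ali != "-") > 0L, drop = FALSE]
  if (length(ids) < 2L) {
    warning("product has a single member (SMS-like record)")
  }
  build_alignment(ids, ali, structures)
}

#' Split a superfamily along a cluster partition
#'
#' @param a a `struct_alignment`
#' @param labels named vector (member -> part label) covering a subset of
#'   members; members absent from `labels` are dropped
#' @param structures named list of structures
#' @return named list of `struct_alignment` objects, one per part (names
#'   are the part labels), all-gap columns removed in each
#' @export
split_superfamily <- function(a, labels, structures) {
  if (length(unique(labels)) < 2L) {
    stop_psnalign("partition must have at least 2 parts",
                  class = "psnalign_argument_error")
  }
  parts <- split(names(labels), labels)
  out <- lapply(parts, function(ids) {
    ali <- a$ali[match(ids, a$ids), , drop = FALSE]
    ali <- ali[, colSums(ali != "-") > 0L, drop = FALSE]
    if (length(ids) < 2L) warning("split part has a single member")
    build_alignment(ids, ali, structures)
  })
  out
}

#' Before/after curation improvement report
#'
#' @param before list(gaps = [gap_stats()], ss = [ss_conservation()])
#' @param after same shape, computed on the curated product(s); for a split,
#'   pass the member-weighted recomputed statistics
#' @return object of class `improvement_report` with the gap and SS deltas
#'   and a regression flag (set when gaps worsened and SS worsened)
#' @export
improvement_report <- function(before, after) {
  d_gap <- after$gaps$mean - before$gaps$mean
  d_ss <- after$ss$percent - before$ss$percent
  structure(list(
    gap_before = before$gaps$mean, gap_after = after$gaps$mean,
    ss_before = before$ss$percent, ss_after = after$ss$percent,
    delta_gap = d_gap, delta_ss = d_ss,
    regression = (d_gap > 0 && d_ss < 0)
  ), class = "improvement_report")
}

#' @export
print.improvement_report <- function(x, ...) {
  cat(sprintf("<improvement_report> gap%%: %.2f -> %.2f (%+.2f); SS%%: %.2f -> %.2f (%+.2f)%s\n",
              x$gap_before, x$gap_after, x$delta_gap,
              x$ss_before, x$ss_after, x$delta_ss,
              if (x$regression) "  ** REGRESSION **" else ""))
  invisible(x)
}

#' Serialize an improvement report to JSON
#' @param x an `improvement_report`
#' @param path optional output path; when NULL the JSON string is returned
#' @export
report_json <- function(x, path = NULL) {
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(j, path); return(invisible(path)) }
  j
}

#' Deserialize an improvement report from JSON
#' @param path or JSON string
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(x, class = "improvement_report")
}
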