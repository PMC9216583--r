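#' @title Synthetic toy-superfamily generator
#' @description Deterministic generator of small domain superfamilies with
#'   known ground truth: ideal-helix geometry, pseudo-side-chain atoms,
#'   rigid-transformed member copies, optional Gaussian coordinate jitter,
#'   and planted curation scenarios (giant insertion, dwarf truncation,
#'   structural outlier, two diverged families). Used by the test suite and
#'   by anyone wanting a download-free end-to-end example.
#' @name fixtures
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fixture specification
#'
#' Geometry: C-alpha atoms on an ideal helix (rise 1.5 A/residue, 100
#' degrees/residue twist, radius 2.3 A); N and C placed 0.5 A from CA along
#' the chain direction, O 0.6 A radially out from C; one pseudo-side-chain
#' CB atom per non-glycine residue, 1.2 A radially outward and alternately
#' 1.25 A up/down along the axis (so the toy helix has a non-trivial
#' side-chain contact pattern at the 4.5 A cutoff).
#'
#' @param n_members number of members
#' @param base_length template length in residues (>= 10)
#' @param noise_sd isotropic Gaussian coordinate jitter, Angstrom
#' @param planted list describing the planted scenario; `type` one of
#'   "none", "giant" (`insert_len`, `position`), "dwarf" (`keep_len`),
#'   "outlier" (`displacement`), "two_families" (`n_b`, `shorten`,
#'   `displacement`, `dwarf_keep` or NULL)
#' @param ss_scramble number of leading template columns at which members'
#'   secondary-structure states are made to disagree (H for odd members, C
#'   for even); emulates a degraded alignment
#' @param seed RNG seed; identical seeds give byte-identical fixture files
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_members = 4L, base_length = 30L, noise_sd = 0,
                         planted = list(type = "none"), ss_scramble = 0L,
                         seed = 1L) {
  stopifnot(base_length >= 10, noise_sd >= 0, n_members >= 1)
  planted$type <- planted$type %||% "none"
  stopifnot(planted$type %in% c("none", "giant", "dwarf", "outlier",
                                "two_families"))
  structure(list(n_members = as.integer(n_members),
                 base_length = as.integer(base_length),
                 noise_sd = noise_sd, planted = planted,
                 ss_scramble = as.integer(ss_scramble),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Canonical planted-giant fixture (8 members, 15-residue insertion)
#'
#' The study condition for giant-trimming recovery: 8 congruent copies of a
#' 12-residue template, the last member carrying a 15-residue inserted
#' segment, secondary structure scrambled at 6 template columns so the
#' superfamily falls in the flagged regime (>50% gaps from one member,
#' <30% conserved SS).
#' @param seed RNG seed
#' @export
fixture_spec_giant <- function(seed = 1L) {
  fixture_spec(n_members = 8L, base_length = 12L, noise_sd = 0,
               planted = list(type = "giant", insert_len = 15L, position = 6L),
               ss_scramble = 6L, seed = seed)
}

#' Canonical two-family + dwarf fixture
#'
#' 3 members of family A (40 residues), 3 of family B (C-terminally
#' shortened by 16 residues and hinge-displaced by 20 A) and one dwarf
#' member truncated to 10 residues.
#' @param seed RNG seed
#' @export
fixture_spec_two_families <- function(seed = 1L) {
  fixture_spec(n_members = 7L, base_length = 40L, noise_sd = 0,
               planted = list(type = "two_families", n_b = 3L, shorten = 16L,
                              displacement = 20, dwarf_keep = 10L),
               seed = seed)
}

#' Canonical structural-outlier fixture
#'
#' 6 members of a 20-residue template; in the last member the second half
#' is rigidly displaced by 45 A, putting its mean CA RMSD to the others
#' (about 15 A after superposition) well beyond the 10 A outlier cutoff.
#' @param seed RNG seed
#' @export
fixture_spec_outlier <- function(seed = 1L) {
  fixture_spec(n_members = 6L, base_length = 20L, noise_sd = 0,
               planted = list(type = "outlier", displacement = 45),
               seed = seed)
}

# --- geometry -------------------------------------------------------------

helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3, z0 = 0) {
  i <- seq_len(n) - 1L
  th <- i * twist * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = z0 + i * rise)
}

# Build a domain_structure from a 1-letter sequence and CA coordinates.
build_toy_structure <- function(domain_id, aa, ca) {
  n <- length(aa)
  stopifnot(nrow(ca) == n)
  unit <- function(v) v / sqrt(sum(v^2))
  rows <- list()
  for (i in seq_len(n)) {
    prev <- if (i > 1L) ca[i - 1L, ] else ca[i, ] - (ca[min(i + 1L, n), ] - ca[i, ])
    nxt <- if (i < n) ca[i + 1L, ] else ca[i, ] + (ca[i, ] - ca[i - 1L, ])
    Np <- ca[i, ] + 0.5 * unit(prev - ca[i, ])
    Cp <- ca[i, ] + 0.5 * unit(nxt - ca[i, ])
    rad <- unit(c(ca[i, 1L], ca[i, 2L], 0))
    Op <- Cp + 0.6 * rad
    at <- rbind(N = Np, CA = ca[i, ], C = Cp, O = Op)
    if (aa[i] != "G") {
      CB <- c(ca[i, 1L:2L] + 1.2 * rad[1L:2L],
              ca[i, 3L] + if (i %% 2L == 0L) 1.25 else -1.25)
      at <- rbind(at, CB = CB)
    }
    rows[[i]] <- data.frame(res_index = i, name = rownames(at),
                            x = at[, 1L], y = at[, 2L], z = at[, 3L],
                            occ = 1, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  resname <- vapply(aa, function(x) bio3d::aa123(x), character(1))
  residues <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                         resname = unname(resname), het = FALSE, aa = aa,
                         stringsAsFactors = FALSE)
  structure(list(domain_id = domain_id, residues = residues, atoms = atoms,
                 cleaned = TRUE, removal_log = character(0)),
            class = "domain_structure")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

jitter_structure <- function(s, sd) {
  if (sd <= 0) return(s)
  n <- nrow(s$atoms)
  s$atoms$x <- s$atoms$x + stats::rnorm(n, 0, sd)
  s$atoms$y <- s$atoms$y + stats::rnorm(n, 0, sd)
  s$atoms$z <- s$atoms$z + stats::rnorm(n, 0, sd)
  s
}

place_member <- function(s, noise_sd) {
  R <- random_rotation()
  t <- stats::runif(3, -20, 20)
  jitter_structure(apply_rigid(s, R, t), noise_sd)
}

subset_structure <- function(s, keep, domain_id = s$domain_id) {
  new_index <- match(s$atoms$res_index, keep)
  atoms <- s$atoms[!is.na(new_index), , drop = FALSE]
  atoms$res_index <- new_index[!is.na(new_index)]
  rownames(atoms) <- NULL
  res <- s$residues[keep, , drop = FALSE]
  res$resno <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(list(domain_id = domain_id, residues = res, atoms = atoms,
                 cleaned = TRUE, removal_log = character(0)),
            class = "domain_structure")
}

# --- generator ------------------------------------------------------------

#' Generate a toy superfamily with known ground truth
#'
#' Writes one PDB per member, the aligned FASTA, a per-member
#' secondary-structure table (`ss.tsv`) and the ground truth as JSON into
#' `dir`, and returns the in-memory objects. Deterministic under
#' `spec$seed`: the same spec yields byte-identical files.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory (created if missing); NULL to skip writing
#' @return list with `structures` (named list), `alignment`
#'   (`struct_alignment`), `ss` (named list of H/E/C strings), `truth`
#'   (list: planted type/member, family labels, expected ACI edges in
#'   column coordinates where defined) and `paths`
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  invisible(with_seed(spec$seed, generate_fixture_impl(spec, dir)))
}

generate_fixture_impl <- function(spec, dir) {
  n <- spec$n_members
  L <- spec$base_length
  ids <- sprintf("mem%d", seq_len(n))
  aa <- sample(.AA20, L, replace = TRUE)
  aa[2L] <- "G"  # guarantee a glycine so the side-chain edge case is exercised
  template <- build_toy_structure("template", aa, helix_ca(L))
  type <- spec$planted$type

  structures <- list()
  rows <- list()          # per-member gapped character vectors
  ss <- list()
  labels <- stats::setNames(rep("A", n), ids)
  planted_member <- NA_character_

  base_ss <- rep("H", L)

  if (type %in% c("none", "giant", "dwarf", "outlier")) {
    p <- if (type == "giant") spec$planted$position %||% floor(L / 2) else L
    ins <- if (type == "giant") spec$planted$insert_len %||% 15L else 0L
    n_columns <- L + ins
    insert_cols <- if (ins > 0L) seq(p + 1L, p + ins) else integer(0)
    base_col <- c(seq_len(p), if (p < L) seq(p + ins + 1L, n_columns))

    for (k in seq_len(n)) {
      id <- ids[k]
      is_planted <- (k == n && type != "none")
      if (is_planted) planted_member <- id
      if (is_planted && type == "giant") {
        aa_ins <- sample(setdiff(.AA20, "G"), ins, replace = TRUE)
        ca <- rbind(helix_ca(L)[seq_len(p), , drop = FALSE],
                    helix_ca(ins, z0 = 50),
                    helix_ca(L)[seq(p + 1L, L), , drop = FALSE])
        s <- build_toy_structure(id, c(aa[seq_len(p)], aa_ins,
                                       if (p < L) aa[seq(p + 1L, L)]), ca)
        row <- rep("-", n_columns)
        row[base_col] <- aa
        row[insert_cols] <- aa_ins
        # base residues keep the template SS, the inserted segment is coil
        ss_str <- c(base_ss[seq_len(p)], rep("C", ins),
                    if (p < L) base_ss[seq(p + 1L, L)])
      } else if (is_planted && type == "dwarf") {
        keep <- spec$planted$keep_len %||% floor(0.3 * L)
        s <- subset_structure(template, seq_len(keep), id)
        row <- rep("-", n_columns)
        row[seq_len(keep)] <- aa[seq_len(keep)]
        ss_str <- base_ss[seq_len(keep)]
      } else if (is_planted && type == "outlier") {
        s <- template
        s$domain_id <- id
        half <- seq(floor(L / 2) + 1L, L)
        disp <- spec$planted$displacement %||% 30
        sel <- s$atoms$res_index %in% half
        s$atoms$x[sel] <- s$atoms$x[sel] + disp
        row <- rep("-", n_columns); row[base_col] <- aa
        ss_str <- base_ss
      } else {
        s <- template
        s$domain_id <- id
        row <- rep("-", n_columns); row[base_col] <- aa
        ss_str <- base_ss
      }
      if (spec$ss_scramble > 0L && length(ss_str) >= spec$ss_scramble) {
        sc <- seq_len(spec$ss_scramble)
        # scramble acts on the member's first template residues
        ss_str[sc] <- if (k %% 2L == 0L) "C" else "H"
      }
      structures[[id]] <- place_member(s, spec$noise_sd)
      rows[[id]] <- row
      ss[[id]] <- paste(ss_str, collapse = "")
    }
    if (!is.na(planted_member)) labels[planted_member] <- type

    # expected ACIs (column coordinates) for rigid-copy scenarios
    expected <- NULL
    if (spec$noise_sd == 0 && type %in% c("none", "giant", "dwarf")) {
      bb <- brute_force_contacts(template, 7.5, "backbone")
      sc <- brute_force_contacts(template, 4.5, "sidechain")
      map_cols <- function(e) {
        if (type == "dwarf") {
          keep <- spec$planted$keep_len %||% floor(0.3 * L)
          e <- e[e[, 1L] <= keep & e[, 2L] <= keep, , drop = FALSE]
        }
        canonical_edges(matrix(base_col[e], ncol = 2L))
      }
      expected <- list(backbone = map_cols(bb), sidechain = map_cols(sc))
    }
  } else {  # two_families
    n_b <- spec$planted$n_b %||% floor(n / 2)
    dwarf_keep <- spec$planted$dwarf_keep
    has_dwarf <- !is.null(dwarf_keep)
    n_a <- n - n_b - as.integer(has_dwarf)
    stopifnot(n_a >= 1L, n_b >= 1L)
    shorten <- spec$planted$shorten %||% floor(0.4 * L)
    disp <- spec$planted$displacement %||% 20
    Lb <- L - shorten
    hinge <- floor(Lb / 2) + 1L

    variant <- subset_structure(template, seq_len(Lb), "variant")
    sel <- variant$atoms$res_index >= hinge
    variant$atoms$x[sel] <- variant$atoms$x[sel] + disp

    n_columns <- L
    for (k in seq_len(n)) {
      id <- ids[k]
      if (k <= n_a) {
        s <- template; s$domain_id <- id
        row <- aa
        ss_str <- base_ss
        labels[id] <- "A"
      } else if (k <= n_a + n_b) {
        s <- variant; s$domain_id <- id
        row <- c(aa[seq_len(Lb)], rep("-", shorten))
        ss_str <- base_ss[seq_len(Lb)]
        labels[id] <- "B"
      } else {
        s <- subset_structure(template, seq_len(dwarf_keep), id)
        row <- c(aa[seq_len(dwarf_keep)], rep("-", L - dwarf_keep))
        ss_str <- base_ss[seq_len(dwarf_keep)]
        labels[id] <- "dwarf"
        planted_member <- id
      }
      structures[[id]] <- place_member(s, spec$noise_sd)
      rows[[id]] <- row
      ss[[id]] <- paste(ss_str, collapse = "")
    }
    expected <- NULL
  }

  ali <- do.call(rbind, rows[ids])
  rownames(ali) <- ids
  alignment <- build_alignment(ids, ali, structures)

  truth <- list(planted = type, planted_member = planted_member,
                family_labels = as.list(labels),
                expected_acis = if (!is.null(expected)) {
                  lapply(expected, function(e) unname(as.data.frame(e)))
                },
                seed = spec$seed)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pdb_paths <- file.path(dir, paste0(ids, ".pdb"))
    for (k in seq_len(n)) write_pdb(structures[[ids[k]]], pdb_paths[k])
    fasta <- file.path(dir, "alignment.fasta")
    write_alignment(alignment, fasta)
    ss_path <- file.path(dir, "ss.tsv")
    writeLines(paste(ids, unlist(ss[ids]), sep = "\t"), ss_path)
    truth_path <- file.path(dir, "truth.json")
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = 10,
                                null = "null"), truth_path)
    paths <- list(pdb = stats::setNames(pdb_paths, ids), alignment = fasta,
                  ss = ss_path, truth = truth_path)
  }
  list(structures = structures, alignment = alignment, ss = ss,
       truth = truth, paths = paths, spec = spec)
}

#' Exhaustive contact-scan oracle
#'
#' Naive O(n^2) enumeration of residue pairs used as the reference for the
#' network builders: for every pair it scans all relevant atom pairs and
#' records a contact when any distance is within the cutoff (inclusive).
#'
#' @param s a `domain_structure`
#' @param cutoff Angstrom
#' @param level "backbone" (CA atoms) or "sidechain" (all atoms except N,
#'   CA, C, O, OXT)
#' @param min_seq_separation minimum |i - j|, default 1
#' @return two-column matrix of residue index pairs (i < j)
#' @export
brute_force_contacts <- function(s, cutoff,
                                 level = c("backbone", "sidechain"),
                                 min_seq_separation = 1L) {
  level <- match.arg(level)
  n <- nrow(s$residues)
  if (cutoff <= 0 || n < 2L) return(canonical_edges(NULL))
  atom_rows <- lapply(seq_len(n), function(i) {
    a <- s$atoms[s$atoms$res_index == i, , drop = FALSE]
    if (level == "backbone") a <- a[a$name == "CA", , drop = FALSE]
    else a <- a[!(a$name %in% .MAINCHAIN_ATOMS), , drop = FALSE]
    as.matrix(a[, c("x", "y", "z")])
  })
  hits <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j - i < min_seq_separation) next
      A <- atom_rows[[i]]; B <- atom_rows[[j]]
      if (nrow(A) == 0L || nrow(B) == 0L) next
      found <- FALSE
      for (ai in seq_len(nrow(A))) {
        for (bi in seq_len(nrow(B))) {
          if (sqrt(sum((A[ai, ] - B[bi, ])^2)) <= cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  canonical_edges(do.call(rbind, hits))
}
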