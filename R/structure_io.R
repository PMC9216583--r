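#' @title Domain structure and alignment I/O
#' @description Reading, cleaning and writing of protein domain structures
#'   (PDB format) and structure-based multiple sequence alignments (aligned
#'   FASTA), plus the column-to-residue correspondence every downstream
#'   module relies on.
#' @name structure_io
NULL

# Non-standard residues with an accepted parent mapping. Anything else that
# is not a standard amino acid (and not GLX/UNK, which are always dropped)
# is removed during cleaning.
.NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Parse a PDB file into a raw domain structure
#'
#' Reads fixed-column ATOM/HETATM records (first MODEL only) and groups atoms
#' into residues keyed by (chain, residue number, insertion code), preserving
#' file order. HETATM residues are retained but flagged so that
#' [clean_structure()] can remove them. For alternate locations of the same
#' atom, the blank/'A' copy is kept when present, otherwise the copy with the
#' highest occupancy.
#'
#' @param path path to a PDB file
#' @param domain_id identifier for the domain; defaults to the file name
#'   without extension
#' @return an object of class `domain_structure`: a list with `domain_id`,
#'   a `residues` data frame (chain, resno, icode, resname, aa, het) and an
#'   `atoms` data frame (res_index, name, x, y, z, occ)
#' @export
parse_pdb <- function(path, domain_id = NULL) {
  if (!file.exists(path)) {
    stop_psnalign("cannot read PDB file: ", path, class = "psnalign_io_error")
  }
  domain_id <- domain_id %||% sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!any(at$type == "ATOM")) {
    stop_psnalign("no ATOM records in ", path, class = "psnalign_empty_error")
  }
  at$elety <- trimws(at$elety)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$o <- ifelse(is.na(at$o), 1, at$o)

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  res_index <- match(rkey, unique(rkey))

  # altloc resolution within (residue, atom name)
  akey <- paste(res_index, at$elety, sep = "\r")
  keep <- logical(nrow(at))
  for (idx in split(seq_len(nrow(at)), akey)) {
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else {
      pref <- idx[at$alt[idx] %in% c("", "A")]
      keep[if (length(pref)) pref[1L] else idx[which.max(at$o[idx])]] <- TRUE
    }
  }
  at <- at[keep, , drop = FALSE]
  res_index <- res_index[keep]

  first <- !duplicated(res_index)
  residues <- data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    icode = at$insert[first],
    resname = at$resid[first],
    het = tapply(at$type == "HETATM", res_index, all)[as.character(res_index[first])],
    stringsAsFactors = FALSE
  )
  rownames(residues) <- NULL
  residues$aa <- suppressWarnings(bio3d::aa321(residues$resname))
  residues$aa[is.na(residues$aa)] <- "X"

  atoms <- data.frame(
    res_index = res_index,
    name = at$elety,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    stringsAsFactors = FALSE
  )
  structure(
    list(domain_id = domain_id, residues = residues, atoms = atoms,
         cleaned = FALSE, removal_log = character(0)),
    class = "domain_structure"
  )
}

#' Clean a domain structure
#'
#' Applies the preprocessing used before any network or superposition step:
#' heteroatom residues are removed, non-standard residues are mapped to their
#' parent residue when a standard mapping exists (e.g. MSE to MET) and
#' removed otherwise, GLX and UNK residues are removed, and residues missing
#' any backbone atom (N, CA, C, O) are removed as incomplete. Residue indices
#' are reassigned consecutively; every removal is recorded in `removal_log`.
#' The operation is idempotent.
#'
#' @param s a `domain_structure`
#' @return a cleaned `domain_structure`; errors if no residues survive
#' @export
clean_structure <- function(s) {
  stopifnot(inherits(s, "domain_structure"))
  res <- s$residues
  log <- s$removal_log

  mapped <- res$resname %in% names(.NONSTANDARD_MAP)
  if (any(mapped)) {
    for (i in which(mapped)) {
      log <- c(log, sprintf("mapped %s -> %s at %s", res$resname[i],
                            .NONSTANDARD_MAP[[res$resname[i]]], res_key(s, i)))
    }
    res$resname[mapped] <- .NONSTANDARD_MAP[res$resname[mapped]]
    res$aa[mapped] <- suppressWarnings(bio3d::aa321(res$resname[mapped]))
    res$het[mapped] <- FALSE
  }

  drop <- rep("", nrow(res))
  drop[res$het] <- "heteroatom"
  drop[drop == "" & res$resname %in% c("GLX", "UNK")] <- "ambiguous/unknown"
  drop[drop == "" & res$aa == "X"] <- "non-standard"

  # backbone completeness
  have_bb <- vapply(seq_len(nrow(res)), function(i) {
    all(.BACKBONE_ATOMS %in% s$atoms$name[s$atoms$res_index == i])
  }, logical(1))
  drop[drop == "" & !have_bb] <- "incomplete"

  for (i in which(drop != "")) {
    log <- c(log, sprintf("removed %s residue %s", drop[i], res_key(s, i)))
  }
  keep <- which(drop == "")
  if (length(keep) == 0L) {
    stop_psnalign("no residues remain after cleaning ", s$domain_id,
                  class = "psnalign_empty_error")
  }
  new_index <- match(s$atoms$res_index, keep)
  atoms <- s$atoms[!is.na(new_index), , drop = FALSE]
  atoms$res_index <- new_index[!is.na(new_index)]
  rownames(atoms) <- NULL
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL

  structure(
    list(domain_id = s$domain_id, residues = res, atoms = atoms,
         cleaned = TRUE, removal_log = log),
    class = "domain_structure"
  )
}

#' One-letter sequence of a domain structure
#' @param s a `domain_structure`
#' @return character scalar
#' @export
structure_sequence <- function(s) paste(s$residues$aa, collapse = "")

#' @export
print.domain_structure <- function(x, ...) {
  cat(sprintf("<domain_structure> %s: %d residues, %d atoms%s\n",
              x$domain_id, nrow(x$residues), nrow(x$atoms),
              if (x$cleaned) " (cleaned)" else ""))
  cat("  sequence:", structure_sequence(x), "\n")
  if (length(x$removal_log)) {
    cat("  cleaning log:", length(x$removal_log), "entries\n")
  }
  invisible(x)
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("<struct_alignment> %d members x %d columns\n",
              length(x$ids), x$n_columns))
  for (i in seq_along(x$ids)) {
    cat(sprintf("  %-12s %s\n", x$ids[i], paste(x$ali[i, ], collapse = "")))
  }
  invisible(x)
}

#' Read a structure-based alignment in aligned-FASTA format
#'
#' Reads the alignment, normalizes '.' gaps to '-', validates that every row
#' has the same number of columns, that no column is all-gap, and that each
#' member's degapped sequence equals its structure's one-letter sequence. The
#' column-to-residue map (`col_map`) is built per member: entry c is the
#' 1-based residue index occupying column c, or NA at a gap.
#'
#' @param path aligned FASTA file ('-' or '.' as gap)
#' @param structures named list of cleaned `domain_structure` objects; every
#'   alignment record id must be present
#' @return an object of class `struct_alignment` with `ids`, `ali` (character
#'   matrix), `n_columns` and `col_map` (list of integer vectors)
#' @export
read_alignment <- function(path, structures) {
  if (!file.exists(path)) {
    stop_psnalign("cannot read alignment file: ", path,
                  class = "psnalign_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    stop_psnalign("no FASTA records in ", path, class = "psnalign_format_error")
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    paste(lines[seq(hdr[k] + 1L, ends[k])][hdr[k] + 1L <= ends[k]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[. ]", "-", gsub("\\s", "", seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop_psnalign("ragged alignment rows in ", path,
                  class = "psnalign_format_error")
  }
  if (anyDuplicated(ids)) {
    stop_psnalign("duplicated record id in ", path,
                  class = "psnalign_format_error")
  }
  unknown <- setdiff(ids, names(structures))
  if (length(unknown)) {
    stop_psnalign("alignment member(s) with no structure: ",
                  paste(unknown, collapse = ", "),
                  class = "psnalign_lookup_error")
  }
  ali <- do.call(rbind, strsplit(seqs, ""))
  rownames(ali) <- ids
  build_alignment(ids, ali, structures)
}

# Assemble and validate a struct_alignment from an id vector and a character
# matrix; shared by read_alignment and the curation editing operations.
build_alignment <- function(ids, ali, structures) {
  n_columns <- ncol(ali)
  if (n_columns == 0L || length(ids) == 0L) {
    stop_psnalign("empty alignment", class = "psnalign_format_error")
  }
  if (any(colSums(ali != "-") == 0L)) {
    stop_psnalign("alignment contains an all-gap column",
                  class = "psnalign_format_error")
  }
  col_map <- vector("list", length(ids))
  names(col_map) <- ids
  for (k in seq_along(ids)) {
    row <- ali[k, ]
    nong <- which(row != "-")
    sseq <- strsplit(structure_sequence(structures[[ids[k]]]), "")[[1]]
    if (length(nong) != length(sseq)) {
      stop_psnalign(sprintf(
        "member %s: alignment has %d residues but structure has %d",
        ids[k], length(nong), length(sseq)),
        class = "psnalign_consistency_error")
    }
    bad <- which(row[nong] != sseq)
    if (length(bad)) {
      stop_psnalign(sprintf(
        "member %s: sequence mismatch at alignment column %d (%s vs structure %s)",
        ids[k], nong[bad[1L]], row[nong[bad[1L]]], sseq[bad[1L]]),
        class = "psnalign_consistency_error")
    }
    cm <- rep(NA_integer_, n_columns)
    cm[nong] <- seq_along(nong)
    col_map[[k]] <- cm
  }
  structure(
    list(ids = ids, ali = ali, n_columns = n_columns, col_map = col_map),
    class = "struct_alignment"
  )
}

#' Validate alignment/structure consistency
#'
#' Re-runs the consistency checks of [read_alignment()] against the current
#' structures: equal row lengths, no all-gap column, degapped rows equal to
#' structure sequences. Used after curation edits.
#'
#' @param a a `struct_alignment`
#' @param structures named list of `domain_structure` objects
#' @return `TRUE` (invisibly); errors on any inconsistency
#' @export
validate_alignment <- function(a, structures) {
  build_alignment(a$ids, a$ali, structures)
  invisible(TRUE)
}

#' Write an alignment in aligned-FASTA format
#' @param a a `struct_alignment`
#' @param path output path
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "struct_alignment"))
  if (length(a$ids) == 0L) {
    stop_psnalign("refusing to write empty alignment",
                  class = "psnalign_format_error")
  }
  bio3d::write.fasta(seqs = a$ali, ids = a$ids, file = path)
  invisible(path)
}

#' Write a domain structure in PDB format
#'
#' Original residue keys (chain, residue number, insertion code) are
#' preserved; nothing is renumbered, so a trimmed structure keeps the
#' numbering of the residues it retained.
#'
#' @param s a `domain_structure`
#' @param path output path
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "domain_structure"))
  at <- s$atoms
  res <- s$residues[at$res_index, , drop = FALSE]
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = res$resno,
    chain = ifelse(res$chain == "", "A", res$chain),
    insert = ifelse(res$icode == "", "", res$icode),
    resid = res$resname,
    elety = at$name,
    o = at$occ,
    b = rep(0, nrow(at))
  )
  invisible(path)
}
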