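# Structure input, contact maps, secondary structure, sequence grouping,
# and the plain-text readers/writers (manifest, MSA FASTA, DSSP override,
# NCBI substitution matrices).

#' Construct a protein structure object
#'
#' Container for one protein chain: one-letter sequence, C-alpha coordinates,
#' per-residue heavy-atom coordinates, binary contact matrix and a secondary
#' structure string over \{H, E, C\}.
#'
#' @param id structure identifier (name + chain).
#' @param sequence one-letter amino-acid string of length L.
#' @param calpha L x 3 matrix of C-alpha coordinates (angstrom).
#' @param atoms list of length L; each element a matrix of heavy-atom
#'   coordinates (>= 1 row, includes the C-alpha).
#' @param contacts optional L x L binary contact matrix; computed with
#'   [compute_contacts()] when `NULL`.
#' @param sstruct optional secondary-structure string; assigned with
#'   [assign_secondary_structure()] when `NULL`.
#' @param resno optional author residue numbers (kept for the PDB writer).
#' @param chain chain identifier.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(id, sequence, calpha, atoms = NULL,
                              contacts = NULL, sstruct = NULL,
                              resno = NULL, chain = "A") {
  L <- nchar(sequence)
  calpha <- as.matrix(calpha)
  stopifnot(nrow(calpha) == L, ncol(calpha) == 3, all(is.finite(calpha)))
  if (is.null(atoms)) atoms <- lapply(seq_len(L), function(i) calpha[i, , drop = FALSE])
  stopifnot(length(atoms) == L)
  x <- structure(list(
    id = id, sequence = sequence, L = L, calpha = calpha, atoms = atoms,
    contacts = contacts, sstruct = sstruct,
    resno = resno %||% seq_len(L), chain = chain
  ), class = "protein_structure")
  if (is.null(x$contacts)) x$contacts <- compute_contacts(x)
  if (is.null(x$sstruct)) x$sstruct <- assign_secondary_structure(x)
  stopifnot(nrow(x$contacts) == L, nchar(x$sstruct) == L)
  x
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure %s> L=%d  contacts=%d  ss=%s...\n",
              x$id, x$L, sum(x$contacts) / 2,
              substr(x$sstruct, 1, min(20, x$L))))
  invisible(x)
}

aa3to1 <- function(resid) {
  out <- bio3d::aa321(resid)
  out[is.na(out) | out == "*"] <- "X"
  out
}

#' Read one chain of a PDB file
#'
#' Parses a PDB file (first model), keeps protein ATOM records of the requested
#' chain, resolves alternate locations (altloc '' or 'A', otherwise highest
#' occupancy) and drops residues lacking a C-alpha atom with a warning.
#'
#' @param path PDB file path.
#' @param chain chain identifier (single character).
#' @param name optional structure name; default basename of `path`.
#' @param cutoff,min_sep contact definition passed to [compute_contacts()].
#' @return a [protein_structure()].
#' @export
read_structure <- function(path, chain = "A", name = NULL,
                           cutoff = 4.5, min_sep = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: ", chain, " in ", path)
  # drop hydrogens and resolve altlocs
  at <- at[!grepl("^H", trimws(at$elesy %||% substr(at$elety, 1, 1))), , drop = FALSE]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")
  if (!any(keep)) keep <- rep(TRUE, nrow(at))
  at <- at[keep, , drop = FALSE]
  key <- paste(at$resno, at$insert %||% "", sep = "_")
  resids <- unique(key)
  calpha <- matrix(NA_real_, length(resids), 3)
  atoms <- vector("list", length(resids))
  seq1 <- character(length(resids))
  resno <- integer(length(resids))
  for (k in seq_along(resids)) {
    rows <- at[key == resids[k], , drop = FALSE]
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    atoms[[k]] <- xyz
    ca <- which(rows$elety == "CA")
    if (length(ca) >= 1) calpha[k, ] <- xyz[ca[1], ]
    seq1[k] <- aa3to1(rows$resid[1])
    resno[k] <- rows$resno[1]
  }
  ok <- is.finite(calpha[, 1])
  if (!all(ok)) {
    warning(sum(!ok), " residue(s) without C-alpha dropped in ",
            basename(path), ":", chain)
  }
  if (!any(ok)) stop("zero usable residues in ", path, ":", chain)
  protein_structure(
    id = paste0(name %||% sub("\\.pdb$", "", basename(path)), "_", chain),
    sequence = paste(seq1[ok], collapse = ""),
    calpha = calpha[ok, , drop = FALSE], atoms = atoms[ok],
    contacts = NULL, sstruct = NULL, resno = resno[ok], chain = chain
  )
}

#' Heavy-atom contact matrix
#'
#' Residues i and j are in contact when any pair of their heavy atoms is
#' closer than `cutoff` angstrom and the sequence separation |i - j| is at
#' least `min_sep`. The matrix is symmetric with a zero diagonal.
#'
#' @param structure a [protein_structure()] (its `atoms` field is used).
#' @param cutoff distance cutoff in angstrom (default 4.5).
#' @param min_sep minimum sequence separation (default 3); trivially adjacent
#'   contacts carry no fold information and would inflate contact overlap.
#' @return L x L binary matrix.
#' @export
compute_contacts <- function(structure, cutoff = 4.5, min_sep = 3) {
  atoms <- structure$atoms
  L <- length(atoms)
  nat <- vapply(atoms, nrow, integer(1))
  if (any(nat == 0)) message("residues with empty heavy-atom lists: ",
                             sum(nat == 0))
  all_xyz <- do.call(rbind, atoms)
  res_of <- rep(seq_len(L), nat)
  cmat <- matrix(0L, L, L)
  if (nrow(all_xyz) == 0) return(cmat)
  # residue-level bounding test via calpha distances keeps this O(close pairs)
  d2 <- as.matrix(stats::dist(all_xyz))^2
  close <- which(d2 < cutoff^2, arr.ind = TRUE)
  ri <- res_of[close[, 1]]
  rj <- res_of[close[, 2]]
  sel <- abs(ri - rj) >= min_sep
  cmat[cbind(ri[sel], rj[sel])] <- 1L
  cmat <- pmax(cmat, t(cmat))
  diag(cmat) <- 0L
  cmat
}

#' Assign secondary structure from C-alpha geometry
#'
#' Internal backbone-geometry assignment based on the C-alpha i,i+2 / i,i+3 /
#' i,i+4 distance signature: helical windows (d(i,i+2) ~ 5.4, d(i,i+3) ~ 5.1,
#' d(i,i+4) ~ 6.2 angstrom) mark residues i..i+4 as H; extended stretches
#' (d(i,i+2) >= 6.3, d(i,i+3) >= 9.0) mark i..i+2 as E; everything else is C.
#' Deterministic for fixed coordinates. A DSSP-style string read with
#' [read_dssp()] may be substituted by assigning to `$sstruct`.
#'
#' @param structure a [protein_structure()] or an L x 3 C-alpha matrix.
#' @return string over \{H, E, C\} of length L (all C when L < 5).
#' @export
assign_secondary_structure <- function(structure) {
  ca <- if (inherits(structure, "protein_structure")) structure$calpha else as.matrix(structure)
  L <- nrow(ca)
  if (L < 5) return(strrep("C", L))
  dk <- function(k) {
    n <- L - k
    if (n < 1) return(numeric(0))
    row_dist(ca[seq_len(n), , drop = FALSE], ca[seq_len(n) + k, , drop = FALSE])
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  ss <- rep("C", L)
  for (i in seq_len(L - 4)) {
    if (d2[i] > 4.6 && d2[i] < 6.1 && d3[i] > 4.2 && d3[i] < 5.9 &&
        d4[i] > 5.2 && d4[i] < 7.2) {
      ss[i:(i + 4)] <- "H"
    }
  }
  for (i in seq_len(L - 3)) {
    if (ss[i] == "C" && d2[i] >= 6.3 && d3[i] >= 9.0) {
      j <- i:min(i + 2, L)
      ss[j][ss[j] == "C"] <- "E"
    }
  }
  paste(ss, collapse = "")
}

#' Read a DSSP file as an H/E/C override string
#'
#' Extracts the summary secondary-structure column of a DSSP output file for
#' one chain and maps H/G/I to H, E/B to E, everything else to C.
#'
#' @param path DSSP file path.
#' @param chain chain identifier.
#' @return string over \{H, E, C\}.
#' @export
read_dssp <- function(path, chain = "A") {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1) stop("not a DSSP file: ", path)
  body <- lines[(start + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  ch <- substr(body, 12, 12)
  aa <- substr(body, 14, 14)
  ss <- substr(body, 17, 17)
  keep <- ch == chain & aa != "!"
  ss <- ss[keep]
  out <- ifelse(ss %in% c("H", "G", "I"), "H",
                ifelse(ss %in% c("E", "B"), "E", "C"))
  paste(out, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Group structures with near-identical sequences
#'
#' Single-linkage grouping of structures under the relation "equal length and
#' Hamming distance <= 1" (identical sequences within one point mutation).
#' The representative of each group is the member with the most resolved
#' residues, ties broken by lexicographic id.
#'
#' @param structures list of [protein_structure()] objects.
#' @return list of `sequence_group` objects with fields `representative_id`,
#'   `member_ids` and `sequence` (the representative's).
#' @export
group_sequences <- function(structures) {
  stopifnot(length(structures) >= 1)
  n <- length(structures)
  seqs <- vapply(structures, `[[`, "", "sequence")
  ids <- vapply(structures, `[[`, "", "id")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (nchar(seqs[i]) == nchar(seqs[j]) &&
          hamming(seqs[i], seqs[j]) <= 1) {
        pi_ <- find(i); pj <- find(j)
        if (pi_ != pj) parent[pj] <- pi_
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    L <- vapply(structures[idx], `[[`, integer(1), "L")
    rep_i <- idx[order(-L, ids[idx])][1]
    structure(list(representative_id = ids[rep_i],
                   member_ids = ids[idx],
                   member_index = idx,
                   representative_index = rep_i,
                   sequence = seqs[rep_i]),
              class = "sequence_group")
  })
}

#' Construct an MSA object
#'
#' @param names ordered character vector of sequence names.
#' @param rows equal-length gapped strings (gap character `-`).
#' @param drop_allgap drop all-gap columns (default TRUE).
#' @return object of class `msa`.
#' @export
msa <- function(names, rows, drop_allgap = TRUE) {
  stopifnot(length(names) == length(rows), length(rows) >= 1)
  if (anyDuplicated(names)) stop("duplicate names in MSA")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("unequal row lengths in MSA")
  m <- do.call(rbind, strsplit(rows, ""))
  if (drop_allgap && ncol(m) > 0) {
    keep <- colSums(m != "-") > 0
    m <- m[, keep, drop = FALSE]
    rows <- apply(m, 1, paste, collapse = "")
  }
  structure(list(names = as.character(names), rows = as.character(rows)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$rows),
              nchar(x$rows[1])))
  invisible(x)
}

#' Number of columns of an MSA
#' @param x an [msa()].
#' @return integer column count.
#' @export
msa_width <- function(x) nchar(x$rows[1])

#' Ungapped sequence of one MSA row
#' @param x an [msa()].
#' @param k row index or name.
#' @return character string without gaps.
#' @export
msa_ungap <- function(x, k) {
  if (is.character(k)) k <- match(k, x$names)
  gsub("-", "", x$rows[k])
}

#' Read an aligned FASTA file
#' @param path FASTA file path.
#' @return an [msa()] (all-gap columns are kept as parsed then dropped by the
#'   constructor's invariant).
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(ss))) != 1) {
    stop("unequal row lengths in ", path)
  }
  msa(names = sub("\\s.*$", "", names(ss)), rows = as.character(ss),
      drop_allgap = FALSE)
}

#' Write an MSA as aligned FASTA
#' @param x an [msa()].
#' @param path output path.
#' @param width line-wrapping width (default 60).
#' @return invisibly, `path`.
#' @export
write_msa <- function(x, path, width = 60) {
  ss <- Biostrings::BStringSet(x$rows)
  names(ss) <- x$names
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a structure manifest
#'
#' Plain text with one "path chain name" triple per line; `#` starts a
#' comment; the name column is optional (defaults to the file basename).
#'
#' @param path manifest path.
#' @return data.frame with columns path, chain, name.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty manifest: ", path)
  parts <- strsplit(lines, "\\s+")
  data.frame(
    path = vapply(parts, `[`, "", 1),
    chain = vapply(parts, function(p) if (length(p) >= 2) p[2] else "A", ""),
    name = vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else sub("\\.pdb$", "", basename(p[1]))
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the usual text layout: comment lines starting with `#`, a header row
#' of residue letters, then one labelled row per residue.
#'
#' @param path matrix file path; `NULL` returns the built-in BLOSUM62.
#' @return numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path = NULL) {
  if (is.null(path)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    return(e$BLOSUM62)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(hdr))))
  rownames(m) <- vapply(rows, `[`, "", 1)
  colnames(m) <- hdr
  m
}

#' Rescale a substitution matrix to [0, 1]
#'
#' Linear rescaling over the 20 standard amino-acid scores so the sequence
#' term is commensurate with structure terms.
#'
#' @param submat substitution matrix (e.g. BLOSUM62).
#' @return rescaled matrix on the standard 20 letters plus X (scored 0).
#' @export
rescale_submat <- function(submat) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  b <- submat[aa, aa]
  b <- (b - min(b)) / (max(b) - min(b))
  out <- matrix(0, 21, 21, dimnames = list(c(aa, "X"), c(aa, "X")))
  out[aa, aa] <- b
  out
}
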