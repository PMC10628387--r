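# Pairwise alignment container and conversions between alignments and MSAs.

#' Construct a pairwise alignment
#'
#' An ordered, gapped correspondence between the residue indices of two
#' proteins. Columns are rows of a two-column integer matrix; `NA` marks a
#' gap. Non-gap indices must be strictly increasing in each column of the
#' matrix, no (gap, gap) columns are allowed, and every residue index appears
#' at most once.
#'
#' @param id1,id2 identifiers of the two proteins.
#' @param pairs integer matrix with two columns (i, j); NA = gap.
#' @return object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(id1, id2, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  validate_pa(pairs)
  structure(list(id1 = id1, id2 = id2, pairs = pairs),
            class = "pairwise_alignment")
}

validate_pa <- function(pairs) {
  if (any(rowSums(is.na(pairs)) == 2)) stop("(gap, gap) column in alignment")
  for (k in 1:2) {
    v <- pairs[!is.na(pairs[, k]), k]
    if (anyDuplicated(v)) stop("residue index repeated in alignment")
    if (is.unsorted(v, strictly = TRUE)) stop("alignment indices not increasing")
  }
  invisible(TRUE)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment %s ~ %s> %d columns, %d aligned\n",
              x$id1, x$id2, nrow(x$pairs), sum(stats::complete.cases(x$pairs))))
  invisible(x)
}

#' Aligned (non-gap) columns of a pairwise alignment
#' @param pa a [pairwise_alignment()].
#' @return two-column matrix of aligned index pairs.
#' @export
pa_aligned <- function(pa) {
  pa$pairs[stats::complete.cases(pa$pairs), , drop = FALSE]
}

#' Identity self-alignment of length L
#' @param id1,id2 identifiers.
#' @param L length.
#' @return a [pairwise_alignment()].
#' @export
identity_pa <- function(id1, id2, L) {
  pairwise_alignment(id1, id2, cbind(seq_len(L), seq_len(L)))
}

#' Build a gapped pairwise alignment from matched index pairs
#'
#' Takes strictly increasing matched pairs and interleaves the unmatched
#' residues of both proteins as gap columns (protein 1's residues emitted
#' before protein 2's between consecutive matches, for determinism).
#'
#' @param id1,id2 identifiers.
#' @param matches k x 2 matrix of strictly increasing matched pairs (possibly
#'   zero rows).
#' @param L1,L2 protein lengths.
#' @return a [pairwise_alignment()].
#' @export
pa_from_matches <- function(id1, id2, matches, L1, L2) {
  matches <- matrix(as.integer(matches), ncol = 2)
  out <- matrix(NA_integer_, 0, 2)
  i <- 1L; j <- 1L
  emit_gaps <- function(out, i_to, j_to, i, j) {
    while (i < i_to) { out <- rbind(out, c(i, NA)); i <- i + 1L }
    while (j < j_to) { out <- rbind(out, c(NA, j)); j <- j + 1L }
    list(out = out, i = i, j = j)
  }
  for (k in seq_len(nrow(matches))) {
    g <- emit_gaps(out, matches[k, 1], matches[k, 2], i, j)
    out <- rbind(g$out, matches[k, ])
    i <- matches[k, 1] + 1L
    j <- matches[k, 2] + 1L
  }
  g <- emit_gaps(out, L1 + 1L, L2 + 1L, i, j)
  pairwise_alignment(id1, id2, g$out)
}

#' Project two rows of an MSA to a pairwise alignment
#'
#' @param x an [msa()].
#' @param p,q row indices or names.
#' @return a [pairwise_alignment()] (columns gapped in both rows are dropped).
#' @export
pa_from_msa <- function(x, p, q) {
  if (is.character(p)) p <- match(p, x$names)
  if (is.character(q)) q <- match(q, x$names)
  rp <- strsplit(x$rows[p], "")[[1]]
  rq <- strsplit(x$rows[q], "")[[1]]
  ip <- ifelse(rp == "-", NA_integer_, cumsum(rp != "-"))
  iq <- ifelse(rq == "-", NA_integer_, cumsum(rq != "-"))
  keep <- !(is.na(ip) & is.na(iq))
  pairwise_alignment(x$names[p], x$names[q], cbind(ip[keep], iq[keep]))
}

#' Build a two-row MSA from a pairwise alignment
#' @param pa a [pairwise_alignment()].
#' @param seq1,seq2 the two ungapped sequences.
#' @return an [msa()] with two rows.
#' @export
msa_from_pa <- function(pa, seq1, seq2) {
  s1 <- strsplit(seq1, "")[[1]]
  s2 <- strsplit(seq2, "")[[1]]
  r1 <- ifelse(is.na(pa$pairs[, 1]), "-", s1[pa$pairs[, 1]])
  r2 <- ifelse(is.na(pa$pairs[, 2]), "-", s2[pa$pairs[, 2]])
  msa(c(pa$id1, pa$id2),
      c(paste(r1, collapse = ""), paste(r2, collapse = "")),
      drop_allgap = FALSE)
}
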