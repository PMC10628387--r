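# MSA comparison scores: symmetric sum-of-pairs and column overlap.

# All aligned residue pairs of an MSA as strings "p r q s" (p < q by
# protein index), restricted to `use` rows (indices into x$names).
msa_pairs <- function(x, use = seq_along(x$names)) {
  cm <- msa_to_colmat(x)
  out <- character(0)
  for (a in seq_along(use)[-length(use)]) {
    for (b in (seq_along(use))[(a + 1):length(use)]) {
      p <- use[a]; q <- use[b]
      sh <- which(!is.na(cm[, p]) & !is.na(cm[, q]))
      if (length(sh)) {
        out <- c(out, paste(a, cm[sh, p], b, cm[sh, q]))
      }
    }
  }
  out
}

match_msas <- function(msaA, msaB) {
  common <- intersect(msaA$names, msaB$names)
  dropped <- setdiff(union(msaA$names, msaB$names), common)
  if (length(dropped)) {
    warning("sequences present in one MSA only dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(common) < 2) stop("fewer than two shared sequences")
  for (nm in common) {
    if (msa_ungap(msaA, nm) != msa_ungap(msaB, nm)) {
      stop("ungapped sequence mismatch for ", nm)
    }
  }
  common
}

#' Sum-of-pairs similarity of two MSAs
#'
#' A pair is an unordered (protein p residue r, protein q residue s), p != q,
#' aligned in the same column. The symmetric score counts pairs aligned in
#' both MSAs, normalized by the geometric mean of the two pair counts (which
#' penalizes overalignment); reference mode normalizes by the reference's
#' pair count only.
#'
#' @param msaA,msaB [msa()] objects over the same sequences (matched by name;
#'   sequences present in only one are dropped with a warning).
#' @param reference `NULL` for the symmetric score, or `"A"`/`"B"` to
#'   normalize by that MSA's pairs.
#' @return list of class `msa_similarity`: `sum_of_pairs`, `shared_pairs`,
#'   `pairs_A`, `pairs_B`.
#' @export
sum_of_pairs <- function(msaA, msaB, reference = NULL) {
  common <- match_msas(msaA, msaB)
  pA <- msa_pairs(msaA, match(common, msaA$names))
  pB <- msa_pairs(msaB, match(common, msaB$names))
  shared <- length(intersect(pA, pB))
  denom <- if (is.null(reference)) {
    sqrt(as.numeric(length(pA)) * length(pB))
  } else if (reference == "A") length(pA) else length(pB)
  structure(list(
    sum_of_pairs = if (denom == 0) 0 else shared / denom,
    shared_pairs = shared, pairs_A = length(pA), pairs_B = length(pB)
  ), class = "msa_similarity")
}

#' Column overlap score of two MSAs
#'
#' Fraction of residues that appear in corresponding columns of the two MSAs.
#' Columns are put in correspondence greedily by maximal shared-residue
#' count (each column used at most once; ties to the leftmost columns); the
#' score is the total number of shared residues over matched columns divided
#' by the total number of residues.
#'
#' @param msaA,msaB [msa()] objects over the same sequences.
#' @return score in [0, 1].
#' @export
column_overlap <- function(msaA, msaB) {
  common <- match_msas(msaA, msaB)
  ia <- match(common, msaA$names)
  ib <- match(common, msaB$names)
  cmA <- msa_to_colmat(msaA)[, ia, drop = FALSE]
  cmB <- msa_to_colmat(msaB)[, ib, drop = FALSE]
  colkeys <- function(cm) {
    lapply(seq_len(nrow(cm)), function(a) {
      v <- cm[a, ]
      paste(which(!is.na(v)), v[!is.na(v)])
    })
  }
  keyA <- colkeys(cmA)
  keyB <- colkeys(cmB)
  nA <- nrow(cmA); nB <- nrow(cmB)
  shared <- matrix(0L, nA, nB)
  for (a in seq_len(nA)) {
    if (length(keyA[[a]]) == 0) next
    for (b in seq_len(nB)) {
      shared[a, b] <- length(intersect(keyA[[a]], keyB[[b]]))
    }
  }
  total <- sum(!is.na(cmA))
  score <- 0
  while (TRUE) {
    mx <- max(shared)
    if (mx <= 0) break
    hit <- which(shared == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- hit[1, 1]; b <- hit[1, 2]
    score <- score + mx
    shared[a, ] <- -1L
    shared[, b] <- -1L
  }
  if (total == 0) 0 else score / total
}

#' Compare two aligned FASTA files
#'
#' Reads two MSAs and prints/returns both comparison scores.
#'
#' @param pathA,pathB aligned FASTA paths.
#' @return data.frame with columns sum_of_pairs, column_overlap,
#'   shared_pairs, pairs_A, pairs_B.
#' @export
compare_msas <- function(pathA, pathB) {
  a <- read_msa(pathA)
  b <- read_msa(pathB)
  sp <- sum_of_pairs(a, b)
  co <- column_overlap(a, b)
  data.frame(sum_of_pairs = sp$sum_of_pairs, column_overlap = co,
             shared_pairs = sp$shared_pairs, pairs_A = sp$pairs_A,
             pairs_B = sp$pairs_B)
}
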