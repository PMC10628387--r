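# The four similarity measures (ali, SI, TM, CO), the hybrid PC_sim, and the
# covariance PCA used to (re)derive its weights.

#' Fixed PC_sim weights
#'
#' Weights of the hybrid similarity: the leading principal component of
#' (aligned fraction, sequence identity, TM-score, contact overlap),
#' PC = (0.84 ali + 0.79 SI + 0.95 TM + 0.95 CO) / 3.53.
#'
#' @return list with w_ali, w_SI, w_TM, w_CO and norm.
#' @export
pc_weights <- function() {
  w <- list(w_ali = 0.84, w_SI = 0.79, w_TM = 0.95, w_CO = 0.95, norm = 3.53)
  stopifnot(abs(w$norm - (w$w_ali + w$w_SI + w$w_TM + w$w_CO)) < 5e-3)
  w
}

#' Aligned fraction
#'
#' Fraction of positions considered homologous (no gaps) with respect to the
#' maximum length of the two proteins; penalizes indels.
#'
#' @param pa a [pairwise_alignment()].
#' @param L1,L2 the two protein lengths.
#' @return ali in [0, 1].
#' @export
aligned_fraction <- function(pa, L1, L2) {
  stopifnot(L1 >= 1, L2 >= 1)
  nrow(pa_aligned(pa)) / max(L1, L2)
}

#' Sequence identity over aligned positions
#'
#' Fraction of aligned (non-gap) positions sharing the same amino acid;
#' indels are not scored. Zero when nothing is aligned.
#'
#' @param pa a [pairwise_alignment()].
#' @param seq1,seq2 the two sequences.
#' @return SI in [0, 1].
#' @export
sequence_identity <- function(pa, seq1, seq2) {
  al <- pa_aligned(pa)
  if (nrow(al) == 0) return(0)
  s1 <- strsplit(seq1, "")[[1]]
  s2 <- strsplit(seq2, "")[[1]]
  if (max(al[, 1]) > length(s1) || max(al[, 2]) > length(s2)) {
    stop("alignment index out of sequence range")
  }
  mean(s1[al[, 1]] == s2[al[, 2]])
}

#' Secondary-structure identity over aligned positions
#' @param pa a [pairwise_alignment()].
#' @param ss1,ss2 secondary-structure strings.
#' @return fraction in [0, 1].
#' @export
ss_identity <- function(pa, ss1, ss2) sequence_identity(pa, ss1, ss2)

tm_from_d <- function(d, d0, L_norm) sum(1 / (1 + (d / d0)^2)) / L_norm

#' TM-score-optimal superposition
#'
#' Determines the rigid transform of protein 1 onto protein 2 that maximizes
#' the TM-score of the aligned columns. The rotation is found
#' self-consistently: iterated least-squares (Kabsch) superposition on a
#' working subset of columns (those with current distance below
#' max(d0, 3 angstrom)), keeping the best-scoring transform, until the subset
#' is stable or 50 iterations; a final direct local maximization of the
#' TM-score over the six rigid degrees of freedom polishes the result.
#' Deterministic.
#'
#' @param pa a [pairwise_alignment()].
#' @param calpha1,calpha2 C-alpha coordinate matrices.
#' @param L_norm normalization length for the TM-score (default: number of
#'   aligned columns, the convention used throughout; `max(L1, L2)` may be
#'   passed instead).
#' @return list of class `superposition`: `rotation`, `translation`,
#'   `distances` (per aligned column), `d0`, `tm`, `iterations`.
#' @export
optimal_superposition <- function(pa, calpha1, calpha2, L_norm = NULL) {
  al <- pa_aligned(pa)
  m <- nrow(al)
  if (m < 3) stop("too few aligned residues (need >= 3)")
  if (is.null(L_norm)) L_norm <- m
  x <- calpha1[al[, 1], , drop = FALSE]
  y <- calpha2[al[, 2], , drop = FALSE]
  d0 <- tm_d0(L_norm)
  dist_of <- function(r, t2) row_dist(apply_transform(x, r, t2), y)
  pack <- function(r, t2, iter) {
    d <- dist_of(r, t2)
    list(rotation = r, translation = t2, distances = d,
         tm = tm_from_d(d, d0, L_norm), iterations = iter)
  }
  # self-consistent refinement from one starting transform: alternate the
  # hard-threshold working subset (columns with d < max(d0, 3 A)) with
  # TM-weighted least squares (weights (1/(1+(d/d0)^2))^2, the stationarity
  # condition of the TM objective), keeping the best transform seen
  refine_from <- function(rot, tra) {
    best <- pack(rot, tra, 1L)
    subset <- integer(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d <- dist_of(rot, tra)
      new_subset <- which(d < max(d0, 3))
      if (length(new_subset) < 3) new_subset <- order(d)[1:3]
      if (identical(new_subset, subset) || iter >= 50) break
      subset <- new_subset
      k <- kabsch(x[subset, , drop = FALSE], y[subset, , drop = FALSE])
      rot <- k$rotation; tra <- k$translation
      cand <- pack(rot, tra, iter)
      if (cand$tm > best$tm) best <- cand
    }
    rot <- best$rotation; tra <- best$translation
    for (it in seq_len(40)) {
      d <- dist_of(rot, tra)
      w <- (1 / (1 + (d / d0)^2))^2
      k <- kabsch(x, y, w)
      rot <- k$rotation; tra <- k$translation
      cand <- pack(rot, tra, iter + it)
      if (cand$tm > best$tm + 1e-15) best <- cand
      else if (it > 3) break
    }
    best
  }
  # seeds: least-squares fit of the full alignment and of its halves; very
  # short alignments (sharp, multimodal TM landscape) add a deterministic
  # rotation grid with centroid-matching translation
  k0 <- kabsch(x, y)
  cands <- list(refine_from(k0$rotation, k0$translation))
  if (m >= 6) {
    h <- floor(m / 2)
    for (idx in list(1:h, (m - h + 1):m)) {
      k <- kabsch(x[idx, , drop = FALSE], y[idx, , drop = FALSE])
      cands <- c(cands, list(refine_from(k$rotation, k$translation)))
    }
  }
  small <- m <= 8
  if (small) {
    cx <- colMeans(x); cy <- colMeans(y)
    for (a in seq(0, 2 * pi, length.out = 7)[-7]) {
      for (b in seq(0, pi, length.out = 4)) {
        for (cc in seq(0, 2 * pi, length.out = 7)[-7]) {
          r <- rotvec_to_matrix(c(0, 0, a)) %*%
            rotvec_to_matrix(c(0, b, 0)) %*% rotvec_to_matrix(c(0, 0, cc))
          cands <- c(cands, list(refine_from(r, as.numeric(cy - r %*% cx))))
        }
      }
    }
  }
  cands <- cands[order(-vapply(cands, `[[`, numeric(1), "tm"))]
  best <- cands[[1]]
  for (ci in seq_len(if (small) min(8, length(cands)) else 1)) {
    base <- cands[[ci]]
    obj <- function(par) {
      r <- rotvec_to_matrix(par[1:3]) %*% base$rotation
      -tm_from_d(dist_of(r, base$translation + par[4:6]), d0, L_norm)
    }
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-14))
    if (-opt$value > best$tm) {
      r <- rotvec_to_matrix(opt$par[1:3]) %*% base$rotation
      best <- pack(r, base$translation + opt$par[4:6], base$iterations)
    }
  }
  structure(c(best, list(d0 = d0, L_norm = L_norm)),
            class = "superposition")
}

#' TM-score from a superposition
#'
#' TM = (1 / L_norm) * sum_i 1 / (1 + (d_i / d0)^2) over aligned superimposed
#' columns, with d0 the length-dependent scale of [tm_d0()].
#'
#' @param superposition a `superposition` from [optimal_superposition()], or a
#'   numeric vector of distances.
#' @param L_norm normalization length (defaults to the superposition's).
#' @return TM in (0, 1].
#' @export
tm_score <- function(superposition, L_norm = NULL) {
  if (inherits(superposition, "superposition")) {
    d <- superposition$distances
    L_norm <- L_norm %||% superposition$L_norm
  } else {
    d <- superposition
    stopifnot(!is.null(L_norm))
  }
  tm_from_d(d, tm_d0(L_norm), L_norm)
}

#' Contact overlap
#'
#' Rotation-free fraction of shared inter-residue contacts,
#' CO = sum_{i<j} C_ij C'_{a(i)a(j)} / sqrt(sum C * sum C'), where a() is the
#' alignment map and gap-aligned residues contribute nothing to the numerator.
#' Normalized so that the maximum value is 1.
#'
#' @param pa a [pairwise_alignment()].
#' @param C1,C2 binary contact matrices of the two proteins.
#' @return CO in [0, 1], or NA with a warning when either protein has no
#'   contacts (undefined).
#' @export
contact_overlap <- function(pa, C1, C2) {
  n1 <- sum(C1[upper.tri(C1)])
  n2 <- sum(C2[upper.tri(C2)])
  if (n1 == 0 || n2 == 0) {
    warning("contact overlap undefined: a protein has zero contacts")
    return(NA_real_)
  }
  al <- pa_aligned(pa)
  if (nrow(al) == 0) return(0)
  s1 <- C1[al[, 1], al[, 1], drop = FALSE]
  s2 <- C2[al[, 2], al[, 2], drop = FALSE]
  num <- sum((s1 * s2)[upper.tri(s1)])
  num / sqrt(n1 * n2)
}

#' Hybrid PC similarity
#'
#' PC = (0.84 ali + 0.79 SI + 0.95 TM + 0.95 CO) / 3.53, the fixed-weight
#' leading-principal-component combination of the four similarity measures.
#'
#' @param ali,SI,TM,CO the four similarities, each in [0, 1].
#' @param weights weight list from [pc_weights()].
#' @return PC in [0, 1].
#' @export
pc_sim <- function(ali, SI, TM, CO, weights = pc_weights()) {
  v <- c(ali, SI, TM, CO)
  if (any(!is.finite(v)) || any(v < -1e-9) || any(v > 1 + 1e-9)) {
    stop("similarities must lie in [0, 1]")
  }
  (weights$w_ali * ali + weights$w_SI * SI +
     weights$w_TM * TM + weights$w_CO * CO) / weights$norm
}

#' All similarity scores of a pairwise alignment
#'
#' Computes ali, SI, TM, CO, PC and the secondary-structure identity for two
#' structures under one alignment.
#'
#' @param pa a [pairwise_alignment()].
#' @param s1,s2 [protein_structure()] objects.
#' @param L_norm TM normalization length (default: aligned columns).
#' @return list of class `similarity_scores` with fields ali, SI, TM, CO, PC,
#'   ss_id, L_ali (CO may be NA when undefined; it enters PC as 0 then).
#' @export
score_pa <- function(pa, s1, s2, L_norm = NULL) {
  L_ali <- nrow(pa_aligned(pa))
  ali <- aligned_fraction(pa, s1$L, s2$L)
  SI <- sequence_identity(pa, s1$sequence, s2$sequence)
  ssid <- ss_identity(pa, s1$sstruct, s2$sstruct)
  if (L_ali >= 3) {
    sup <- optimal_superposition(pa, s1$calpha, s2$calpha, L_norm)
    TM <- sup$tm
  } else {
    TM <- 0
  }
  CO <- suppressWarnings(contact_overlap(pa, s1$contacts, s2$contacts))
  PC <- pc_sim(ali, SI, TM, ifelse(is.na(CO), 0, CO))
  structure(list(ali = ali, SI = SI, TM = TM, CO = CO, PC = PC,
                 ss_id = ssid, L_ali = L_ali),
            class = "similarity_scores")
}

#' Leading principal component of a similarity score table
#'
#' Covariance PCA (no standardization; scores already live on [0, 1]) of a
#' table of (ali, SI, TM, CO) rows. The first component's sign is fixed to be
#' all-positive when possible, otherwise to have a positive sum.
#'
#' @param score_table numeric matrix or data.frame with >= 4 rows and 4
#'   columns.
#' @return list with `loads` (unit 4-vector) and `variance_fractions`
#'   (length 4).
#' @export
pca_loads <- function(score_table) {
  m <- as.matrix(score_table)
  stopifnot(ncol(m) == 4)
  if (nrow(m) < 4) stop("need at least 4 rows")
  cv <- stats::cov(m)
  if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-12) {
    stop("degenerate covariance")
  }
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (all(v <= 1e-12)) v <- -v else if (sum(v) < 0) v <- -v
  list(loads = v, variance_fractions = e$values / sum(e$values))
}

#' Write a pairwise similarity score table
#'
#' Whitespace-separated columns `id1 id2 ali SI SS TM CO PC` (SS is the
#' secondary-structure identity), one row per pair.
#'
#' @param scores data.frame with columns id1, id2, ali, SI, SS, TM, CO, PC.
#' @param path output path (conventionally suffixed `.sim`).
#' @return invisibly, `path`.
#' @export
write_sim_table <- function(scores, path) {
  df <- scores[, c("id1", "id2", "ali", "SI", "SS", "TM", "CO", "PC")]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
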