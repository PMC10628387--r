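# Structure-guided modification of pairwise alignments: secondary-structure
# gap relocation (SS_ali), neighbor-frame refinement targeting TM, CO or
# PC_sim, and the de novo pairwise aligner used when no input MSA exists.

sse_runs <- function(ss) {
  v <- strsplit(ss, "")[[1]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values %in% c("H", "E")
  data.frame(start = starts[keep], end = ends[keep], type = r$values[keep])
}

# Move one gap run (columns `cols` of `pairs`, gapped in row `grow`) to the
# nearer end of the SSE [s, e] of the other row. Returns modified pairs.
move_gap_run <- function(pairs, cols, grow, s, e) {
  orow <- 3 - grow
  b1 <- pairs[cols[1], orow]
  b2 <- pairs[cols[length(cols)], orow]
  left <- b1 - s
  right <- e - b2
  len <- length(cols)
  if (left <= right) {
    region <- which(!is.na(pairs[, orow]) & pairs[, orow] >= s &
                      pairs[, orow] <= b2)
    v <- pairs[region, grow]
    pairs[region, grow] <- c(utils::tail(v, len), utils::head(v, length(v) - len))
  } else {
    region <- which(!is.na(pairs[, orow]) & pairs[, orow] >= b1 &
                      pairs[, orow] <= e)
    v <- pairs[region, grow]
    pairs[region, grow] <- c(utils::tail(v, length(v) - len), utils::head(v, len))
  }
  pairs
}

#' Secondary-structure gap relocation (SS_ali)
#'
#' A gap opened strictly inside a secondary-structure element is moved to the
#' nearer end of that element (fewer shifted positions; ties to the
#' N-terminal end), reflecting that a deletion inside an SSE rearranges the
#' structure so the structural correspondence shifts to the element boundary.
#' Sequence identity and TM-score are computed for the input and the modified
#' alignment and the larger of each is reported; when the modified TM-score
#' is higher, the contact overlap is also taken from the modified alignment.
#'
#' @param pa a [pairwise_alignment()].
#' @param s1,s2 [protein_structure()] objects (sstruct fields are used).
#' @return list of class `refinement_result`: `refined` (the modified
#'   alignment when its TM-score is higher, otherwise the input), `modified`
#'   (the gap-relocated alignment itself), `scores_in`, `scores_out` (with
#'   the max-selection rule applied), `target` ("SS"), `iterations`.
#' @export
ss_realign <- function(pa, s1, s2) {
  pairs <- pa$pairs
  sses <- list(sse_runs(s2$sstruct), sse_runs(s1$sstruct))
  changed <- TRUE
  iter <- 0L
  while (changed && iter < 10L) {
    changed <- FALSE
    iter <- iter + 1L
    for (grow in 1:2) {
      gap <- is.na(pairs[, grow])
      if (!any(gap)) next
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        cols <- starts[k]:ends[k]
        orow <- 3 - grow
        js <- pairs[cols, orow]
        if (any(is.na(js))) next
        sse <- sses[[grow]]
        hit <- which(sse$start < min(js) & sse$end > max(js))
        if (length(hit) != 1) next
        pairs2 <- move_gap_run(pairs, cols, grow, sse$start[hit], sse$end[hit])
        if (!identical(pairs2, pairs)) {
          pairs <- pairs2
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  mod <- pairwise_alignment(pa$id1, pa$id2, pairs)
  sc_in <- score_pa(pa, s1, s2)
  sc_mod <- score_pa(mod, s1, s2)
  out <- sc_in
  out$SI <- max(sc_in$SI, sc_mod$SI)
  out$TM <- max(sc_in$TM, sc_mod$TM)
  take_mod <- sc_mod$TM > sc_in$TM
  if (take_mod) out$CO <- sc_mod$CO
  co <- ifelse(is.na(out$CO), 0, out$CO)
  out$PC <- pc_sim(out$ali, out$SI, out$TM, co)
  structure(list(refined = if (take_mod) mod else pa, modified = mod,
                 scores_in = sc_in, scores_out = out,
                 target = "SS", iterations = iter),
            class = "refinement_result")
}

shared_contact_counts <- function(pa, C1, C2) {
  al <- pa_aligned(pa)
  if (nrow(al) == 0) return(matrix(0, nrow(C1), nrow(C2)))
  C1[, al[, 1], drop = FALSE] %*% C2[al[, 2], , drop = FALSE]
}

#' Nearest-residue map under a target score
#'
#' For each residue of each protein, finds the residue of the other protein
#' that maximizes the target contribution: minimal C-alpha distance after the
#' current superposition (target "TM"), maximal count of shared contacts
#' contributed if the two residues were aligned given the current alignment
#' (target "CO"), or the weighted per-residue PC combination (target "PC").
#' Residues with no positive contribution map to NONE (NA). Two residues that
#' are mutual nearest residues form a double match.
#'
#' @param pa a [pairwise_alignment()] providing the context.
#' @param s1,s2 [protein_structure()] objects.
#' @param target one of "TM", "CO", "PC".
#' @param sup superposition from [optimal_superposition()] (required for TM
#'   and PC targets; computed from `pa` when NULL).
#' @return list of class `neighbor_map`: `n1`, `n2` (nearest indices, NA =
#'   NONE) and `double` (k x 2 matrix of double matches, ordered by i).
#' @export
nearest_map <- function(pa, s1, s2, target = c("TM", "CO", "PC"), sup = NULL) {
  target <- match.arg(target)
  if (target %in% c("TM", "PC") && is.null(sup)) {
    if (nrow(pa_aligned(pa)) < 3) stop("missing superposition: too few aligned residues")
    sup <- optimal_superposition(pa, s1$calpha, s2$calpha)
  }
  score <- matrix(0, s1$L, s2$L)
  if (target == "TM") {
    x <- apply_transform(s1$calpha, sup$rotation, sup$translation)
    dmat <- outer(rowSums(x^2), rowSums(s2$calpha^2), `+`) -
      2 * x %*% t(s2$calpha)
    dmat[dmat < 0] <- 0
    score <- -sqrt(dmat)
    n1 <- apply(score, 1, which.max)
    n2 <- apply(score, 2, which.max)
  } else {
    sc <- shared_contact_counts(pa, s1$contacts, s2$contacts)
    if (target == "CO") {
      score <- sc
    } else {
      w <- pc_weights()
      x <- apply_transform(s1$calpha, sup$rotation, sup$translation)
      dmat <- sqrt(pmax(outer(rowSums(x^2), rowSums(s2$calpha^2), `+`) -
                          2 * x %*% t(s2$calpha), 0))
      aa_eq <- outer(strsplit(s1$sequence, "")[[1]],
                     strsplit(s2$sequence, "")[[1]], `==`)
      maxdeg <- max(rowSums(s1$contacts), rowSums(s2$contacts), 1)
      score <- (w$w_SI * aa_eq + w$w_TM * (dmat < sup$d0) +
                  w$w_CO * sc / maxdeg) / (w$w_SI + w$w_TM + w$w_CO)
    }
    n1 <- apply(score, 1, function(r) {
      if (max(r) <= 0) NA_integer_ else which.max(r)
    })
    n2 <- apply(score, 2, function(r) {
      if (max(r) <= 0) NA_integer_ else which.max(r)
    })
    # ties keep the current partner (modify the input as little as possible)
    al0 <- pa_aligned(pa)
    for (k in seq_len(nrow(al0))) {
      i <- al0[k, 1]; j <- al0[k, 2]
      if (!is.na(n1[i]) && score[i, j] >= score[i, n1[i]]) n1[i] <- j
      if (!is.na(n2[j]) && score[i, j] >= score[n2[j], j]) n2[j] <- i
    }
  }
  dbl <- which(!is.na(n1) & !is.na(n2[pmax(n1, 1L)]) &
                 n2[pmax(n1, 1L)] == seq_len(s1$L))
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 double = cbind(i = dbl, j = as.integer(n1[dbl]))),
            class = "neighbor_map")
}

# Frames-and-fill: keep double matches already aligned in `pa` as frames and
# insert order-consistent double matches between them, left to right.
frames_fill <- function(pa, dbl, L1, L2) {
  al <- pa_aligned(pa)
  key <- paste(al[, 1], al[, 2])
  dkey <- paste(dbl[, 1], dbl[, 2])
  is_frame <- dkey %in% key
  sel <- matrix(integer(0), 0, 2)
  last_i <- 0L; last_j <- 0L
  frames <- dbl[is_frame, , drop = FALSE]
  for (k in seq_len(nrow(dbl))) {
    i <- dbl[k, 1]; j <- dbl[k, 2]
    if (i <= last_i || j <= last_j) next
    if (is_frame[k]) {
      sel <- rbind(sel, c(i, j)); last_i <- i; last_j <- j
    } else {
      # next frame bound
      nf <- frames[frames[, 1] > last_i, , drop = FALSE]
      ni <- if (nrow(nf)) nf[1, 1] else L1 + 1L
      nj <- if (nrow(nf)) nf[1, 2] else L2 + 1L
      if (i < ni && j < nj) {
        sel <- rbind(sel, c(i, j)); last_i <- i; last_j <- j
      }
    }
  }
  pa_from_matches(pa$id1, pa$id2, sel, L1, L2)
}

target_score <- function(sc, target) {
  switch(target, TM = sc$TM, CO = ifelse(is.na(sc$CO), 0, sc$CO), PC = sc$PC,
         SS = sc$PC)
}

#' Neighbor-frame refinement of a pairwise alignment
#'
#' Iteratively modifies the input alignment to increase a target score
#' without scoring gaps: (i) nearest residues under the target are computed
#' from the current alignment, (ii) mutual nearest residues (double matches)
#' that are already aligned become fixed frames, (iii) double matches that
#' fall sequentially between consecutive frames are aligned left to right,
#' and the procedure repeats with recomputed neighbors until the alignment is
#' unchanged or `max_iter` passes. The better of (refined, input) under the
#' target score is returned (keep-better guarantee).
#'
#' @param pa a [pairwise_alignment()].
#' @param s1,s2 [protein_structure()] objects.
#' @param target one of "TM", "CO", "PC".
#' @param max_iter maximum refinement passes (default 5).
#' @return a `refinement_result` (see [ss_realign()]).
#' @export
refine_pa <- function(pa, s1, s2, target = c("TM", "CO", "PC"), max_iter = 5) {
  target <- match.arg(target)
  cur <- pa
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sup <- NULL
    if (target %in% c("TM", "PC")) {
      if (nrow(pa_aligned(cur)) < 3) break
      sup <- optimal_superposition(cur, s1$calpha, s2$calpha)
    }
    nm <- nearest_map(cur, s1, s2, target, sup)
    if (nrow(nm$double) == 0) break
    new <- frames_fill(cur, nm$double, s1$L, s2$L)
    if (identical(new$pairs, cur$pairs)) break
    cur <- new
  }
  sc_in <- score_pa(pa, s1, s2)
  sc_cur <- score_pa(cur, s1, s2)
  # ties go to the input: the refinement must not modify without gain
  if (target_score(sc_cur, target) > target_score(sc_in, target)) {
    refined <- cur; scores_out <- sc_cur
  } else {
    refined <- pa; scores_out <- sc_in
  }
  structure(list(refined = refined, scores_in = sc_in,
                 scores_out = scores_out, target = target,
                 iterations = iter),
            class = "refinement_result")
}

#' Contact-vector similarity of two residues
#'
#' Similarity of the signed sequence-offset multisets of the contacts of
#' residue i in protein 1 and residue j in protein 2:
#' 1 - |multiset symmetric difference| / (deg(i) + deg(j)); 0 when both
#' degrees are zero.
#'
#' @param C1,C2 binary contact matrices.
#' @return L1 x L2 matrix of similarities in [0, 1].
#' @export
contact_vector_similarity <- function(C1, C2) {
  off1 <- lapply(seq_len(nrow(C1)), function(i) which(C1[i, ] == 1) - i)
  off2 <- lapply(seq_len(nrow(C2)), function(j) which(C2[j, ] == 1) - j)
  out <- matrix(0, nrow(C1), nrow(C2))
  for (i in seq_along(off1)) {
    a <- off1[[i]]
    ta <- table(a)
    for (j in seq_along(off2)) {
      b <- off2[[j]]
      if (length(a) == 0 && length(b) == 0) next
      tb <- table(b)
      keys <- union(names(ta), names(tb))
      symdiff <- sum(abs(ifelse(is.na(ta[keys]), 0, ta[keys]) -
                           ifelse(is.na(tb[keys]), 0, tb[keys])))
      out[i, j] <- 1 - symdiff / (length(a) + length(b))
    }
  }
  out
}

# Affine-gap global (Gotoh) alignment maximizing sum of S[i, j] scores.
# Deterministic traceback preferring diagonal > up (gap in 2) > left.
nw_affine <- function(S, gap_open = 0.35, gap_ext = 0.05) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - (j - 1) * gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- S[i, j] + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open, Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open, Iy[i + 1, j] - gap_ext)
    }
  }
  # traceback
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  cols <- matrix(integer(0), 0, 2)
  while (i > 0 || j > 0) {
    if (i == 0) state <- 3 else if (j == 0) state <- 2
    if (state == 1) {
      cols <- rbind(c(i, j), cols)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2) {
      cols <- rbind(c(i, NA), cols)
      from_m <- M[i, j + 1] - gap_open
      from_ix <- Ix[i, j + 1] - gap_ext
      i <- i - 1
      state <- if (from_m >= from_ix) 1 else 2
    } else {
      cols <- rbind(c(NA, j), cols)
      from_m <- M[i + 1, j] - gap_open
      from_iy <- Iy[i + 1, j] - gap_ext
      j <- j - 1
      state <- if (from_m >= from_iy) 1 else 3
    }
  }
  cols
}

#' De novo pairwise alignment of two structures
#'
#' Global dynamic programming with affine gaps over the position-pair score
#' S(i, j) = (w_SI bhat(aa_i, aa_j) + w_TM [ss_i == ss_j] + w_CO cvs(i, j))
#' / (w_SI + w_TM + w_CO), where bhat is the substitution matrix rescaled to
#' [0, 1], the secondary-structure identity stands in for the TM term and the
#' contact-vector similarity of [contact_vector_similarity()] stands in for
#' the contact overlap, so no starting alignment or superposition is needed.
#'
#' @param s1,s2 [protein_structure()] objects.
#' @param submat substitution matrix (default BLOSUM62).
#' @param gap_open,gap_ext affine gap parameters on the [0, 1] score scale.
#' @return a [pairwise_alignment()].
#' @export
denovo_pa <- function(s1, s2, submat = NULL, gap_open = 0.35, gap_ext = 0.05) {
  bhat <- rescale_submat(submat %||% read_substitution_matrix())
  a1 <- strsplit(s1$sequence, "")[[1]]
  a2 <- strsplit(s2$sequence, "")[[1]]
  a1[!a1 %in% rownames(bhat)] <- "X"
  a2[!a2 %in% rownames(bhat)] <- "X"
  w <- pc_weights()
  S <- (w$w_SI * bhat[a1, a2, drop = FALSE] +
          w$w_TM * outer(strsplit(s1$sstruct, "")[[1]],
                         strsplit(s2$sstruct, "")[[1]], `==`) +
          w$w_CO * contact_vector_similarity(s1$contacts, s2$contacts)) /
    (w$w_SI + w$w_TM + w$w_CO)
  cols <- nw_affine(S, gap_open, gap_ext)
  pairwise_alignment(s1$id, s2$id, cols)
}
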