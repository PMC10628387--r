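# Iterative progressive multiple alignment: superimpose all structures on
# the current MSA, infer PC_div divergences, build an average-linkage guide
# tree, re-align clusters leaf-to-root with a PC_sim-based profile score, and
# keep the iteration with the largest average PC_sim.

#' Average-linkage (UPGMA) guide tree
#'
#' Merge sequence from average-linkage clustering of a divergence matrix;
#' node heights are half the cluster-average divergence. Deterministic.
#'
#' @param div_matrix symmetric divergence matrix with zero diagonal (NA not
#'   allowed; impute first with [divergence_matrix()]).
#' @param labels leaf labels (default: dimnames).
#' @return list of class `guide_tree`: `merge` (hclust convention), `height`
#'   (half-average divergences), `labels`, `order`, `hclust` (the underlying
#'   object with halved heights).
#' @export
build_guide_tree <- function(div_matrix, labels = NULL) {
  if (any(is.na(div_matrix))) stop("divergence matrix contains NA; impute first")
  labels <- labels %||% rownames(div_matrix) %||%
    paste0("S", seq_len(nrow(div_matrix)))
  hc <- stats::hclust(stats::as.dist(div_matrix), method = "average")
  hc$height <- hc$height / 2
  hc$labels <- labels
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 order = hc$order, hclust = hc),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("<guide_tree> %d leaves, %d merges\n", length(x$labels),
              nrow(x$merge)))
  invisible(x)
}

#' Consensus superposition of all structures on an MSA
#'
#' Rigid transforms placing every structure in a common frame: the medoid
#' (structure with the largest summed pairwise PC_sim, or the most central
#' by shared columns when scores are not supplied) is fixed, the others are
#' superimposed onto the evolving column-average of the transformed C-alpha
#' coordinates, iterating until the summed pairwise TM-score stabilizes
#' (change < 1e-6) or 20 rounds; the best transform set seen is kept, so the
#' reported summed TM is nondecreasing over rounds.
#'
#' @param x an [msa()] covering all structures.
#' @param structures list of [protein_structure()] objects named/ordered as
#'   the MSA rows.
#' @param pair_pc optional matrix of pairwise PC_sim used to pick the medoid.
#' @return list of class `multi_superposition`: `transforms` (per structure:
#'   rotation, translation), `medoid`, `sum_tm`, `rounds`.
#' @export
multiple_superposition <- function(x, structures, pair_pc = NULL) {
  n <- length(structures)
  stopifnot(n == length(x$rows))
  W <- msa_width(x)
  resmap <- vapply(seq_len(n), function(k) {
    r <- strsplit(x$rows[k], "")[[1]]
    ifelse(r == "-", NA_integer_, cumsum(r != "-"))
  }, integer(W))
  resmap <- matrix(resmap, nrow = W)
  if (is.null(pair_pc)) {
    medoid <- which.max(vapply(seq_len(n), function(k) {
      sum(!is.na(resmap[, k]) & rowSums(!is.na(resmap)) > 1)
    }, numeric(1)))
  } else {
    medoid <- which.max(rowSums(pair_pc, na.rm = TRUE))
  }
  transforms <- lapply(seq_len(n), function(k) {
    list(rotation = diag(3), translation = c(0, 0, 0))
  })
  # initialize: pairwise superposition onto the medoid
  for (k in seq_len(n)) {
    if (k == medoid) next
    sh <- which(!is.na(resmap[, k]) & !is.na(resmap[, medoid]))
    if (length(sh) >= 3) {
      pa <- pairwise_alignment(structures[[k]]$id, structures[[medoid]]$id,
                               cbind(resmap[sh, k], resmap[sh, medoid]))
      sup <- optimal_superposition(pa, structures[[k]]$calpha,
                                   structures[[medoid]]$calpha)
      transforms[[k]] <- list(rotation = sup$rotation,
                              translation = sup$translation)
    } else {
      warning("structure ", structures[[k]]$id,
              " shares <3 columns with the medoid; left untransformed")
    }
  }
  placed <- function(tr) {
    lapply(seq_len(n), function(k) {
      apply_transform(structures[[k]]$calpha, tr[[k]]$rotation,
                      tr[[k]]$translation)
    })
  }
  sum_tm <- function(coords) {
    s <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      sh <- which(!is.na(resmap[, a]) & !is.na(resmap[, b]))
      if (length(sh) == 0) next
      d <- row_dist(coords[[a]][resmap[sh, a], , drop = FALSE],
                    coords[[b]][resmap[sh, b], , drop = FALSE])
      s <- s + tm_from_d(d, tm_d0(length(sh)), length(sh))
    }
    s
  }
  best <- list(transforms = transforms,
               sum_tm = sum_tm(placed(transforms)))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    coords <- placed(transforms)
    consensus <- matrix(NA_real_, W, 3)
    for (c_ in seq_len(W)) {
      pres <- which(!is.na(resmap[c_, ]))
      if (length(pres) == 0) next
      consensus[c_, ] <- colMeans(do.call(rbind, lapply(pres, function(k) {
        coords[[k]][resmap[c_, k], ]
      })))
    }
    new_tr <- transforms
    for (k in seq_len(n)) {
      sh <- which(!is.na(resmap[, k]) & is.finite(consensus[, 1]))
      if (length(sh) < 3) next
      kb <- kabsch(structures[[k]]$calpha[resmap[sh, k], , drop = FALSE],
                   consensus[sh, , drop = FALSE])
      new_tr[[k]] <- list(rotation = kb$rotation, translation = kb$translation)
    }
    st <- sum_tm(placed(new_tr))
    improved <- st > best$sum_tm + 1e-6
    if (st > best$sum_tm) best <- list(transforms = new_tr, sum_tm = st)
    transforms <- new_tr
    if (!improved || rounds >= 20L) break
  }
  structure(list(transforms = best$transforms, medoid = medoid,
                 sum_tm = best$sum_tm, rounds = rounds),
            class = "multi_superposition")
}

# Pairwise score table for all unordered pairs projected out of an MSA.
msa_pair_scores <- function(x, structures) {
  n <- length(structures)
  out <- list()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    pa <- pa_from_msa(x, a, b)
    sc <- score_pa(pa, structures[[a]], structures[[b]])
    out[[length(out) + 1]] <- data.frame(
      id1 = x$names[a], id2 = x$names[b], ali = sc$ali, SI = sc$SI,
      SS = sc$ss_id, TM = sc$TM, CO = ifelse(is.na(sc$CO), NA, sc$CO),
      PC = sc$PC, L_ali = sc$L_ali, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Per-pair position score matrices for profile alignment, from the current
# MSA and consensus superposition.
pair_position_scores <- function(x, structures, msup, bonus = 0.1) {
  n <- length(structures)
  w <- pc_weights()
  coords <- lapply(seq_len(n), function(k) {
    apply_transform(structures[[k]]$calpha, msup$transforms[[k]]$rotation,
                    msup$transforms[[k]]$translation)
  })
  aa <- lapply(structures, function(s) strsplit(s$sequence, "")[[1]])
  bhat <- rescale_submat(read_substitution_matrix())
  for (k in seq_len(n)) aa[[k]][!aa[[k]] %in% rownames(bhat)] <- "X"
  mats <- vector("list", n * n)
  dim(mats) <- c(n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    pa <- pa_from_msa(x, a, b)
    al <- pa_aligned(pa)
    L_ali <- max(nrow(al), 1)
    d0 <- tm_d0(L_ali)
    dmat <- sqrt(pmax(outer(rowSums(coords[[a]]^2),
                            rowSums(coords[[b]]^2), `+`) -
                        2 * coords[[a]] %*% t(coords[[b]]), 0))
    sc <- shared_contact_counts(pa, structures[[a]]$contacts,
                                structures[[b]]$contacts)
    maxdeg <- max(rowSums(structures[[a]]$contacts),
                  rowSums(structures[[b]]$contacts), 1)
    alb <- matrix(0, structures[[a]]$L, structures[[b]]$L)
    if (nrow(al) > 0) alb[al] <- 1
    m <- (w$w_SI * bhat[aa[[a]], aa[[b]], drop = FALSE] +
            w$w_TM * 1 / (1 + (dmat / d0)^2) +
            w$w_CO * sc / maxdeg +
            bonus * alb) / (w$w_SI + w$w_TM + w$w_CO)
    mats[[a, b]] <- m
    mats[[b, a]] <- t(m)
  }
  mats
}

#' Align two internally frozen clusters of an MSA
#'
#' Global dynamic programming with affine gaps over column pairs. The score
#' of a column pair is the mean over cross-pairs of member proteins of a
#' PC_sim-style per-position score (rescaled substitution score, TM-style
#' superposition distance term, shared-contact term, and a bonus for pairs
#' aligned in the current MSA); gapped members contribute zero. Columns of
#' each cluster are never split.
#'
#' @param colsA,colsB column lists: each a matrix (columns x proteins) of
#'   residue indices with NA for gaps, over the same full protein set.
#' @param posmat per-pair position score matrices from
#'   `pair_position_scores`.
#' @param membersA,membersB protein indices present in each cluster.
#' @param gap_open,gap_ext affine gap parameters.
#' @return merged column matrix (columns x proteins).
#' @noRd
align_clusters <- function(colsA, colsB, posmat, membersA, membersB,
                           gap_open = 0.35, gap_ext = 0.05) {
  nA <- nrow(colsA); nB <- nrow(colsB)
  S <- matrix(0, nA, nB)
  npair <- length(membersA) * length(membersB)
  for (p in membersA) for (q in membersB) {
    m <- posmat[[p, q]]
    ia <- colsA[, p]
    jb <- colsB[, q]
    contrib <- matrix(0, nA, nB)
    ok_i <- !is.na(ia); ok_j <- !is.na(jb)
    if (any(ok_i) && any(ok_j)) {
      contrib[ok_i, ok_j] <- m[ia[ok_i], jb[ok_j], drop = FALSE]
    }
    S <- S + contrib
  }
  S <- S / npair
  tb <- nw_affine(S, gap_open, gap_ext)
  merged <- matrix(NA_integer_, nrow(tb), ncol(colsA))
  ai <- tb[, 1]; bj <- tb[, 2]
  merged[!is.na(ai), membersA] <- colsA[ai[!is.na(ai)], membersA, drop = FALSE]
  merged[!is.na(bj), membersB] <- colsB[bj[!is.na(bj)], membersB, drop = FALSE]
  merged
}

msa_to_colmat <- function(x) {
  W <- msa_width(x)
  out <- vapply(seq_along(x$rows), function(k) {
    r <- strsplit(x$rows[k], "")[[1]]
    ifelse(r == "-", NA_integer_, cumsum(r != "-"))
  }, integer(W))
  matrix(out, nrow = W)
}

colmat_to_msa <- function(cm, names, sequences) {
  seqs <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  rows <- vapply(seq_along(names), function(p) {
    chars <- ifelse(is.na(cm[, p]), "-", "")
    idx <- cm[, p]
    chars[!is.na(idx)] <- seqs[[p]][idx[!is.na(idx)]]
    paste(chars, collapse = "")
  }, "")
  msa(names, rows)
}

# One full progressive pass: guide tree + leaf-to-root profile merges.
progressive_pass <- function(x, structures, msup, bonus = 0.1,
                             gap_open = 0.35, gap_ext = 0.05) {
  n <- length(structures)
  scores <- msa_pair_scores(x, structures)
  scores$PCdiv <- pc_divergence(scores$PC, pmax(scores$L_ali, 1))
  dm <- divergence_matrix(scores, "PCdiv", ids = x$names)
  tree <- build_guide_tree(dm$matrix)
  posmat <- pair_position_scores(x, structures, msup, bonus)
  # leaves: single ungapped columns
  clusters <- lapply(seq_len(n), function(k) {
    cm <- matrix(NA_integer_, structures[[k]]$L, n)
    cm[, k] <- seq_len(structures[[k]]$L)
    list(cols = cm, members = k)
  })
  node_cluster <- vector("list", nrow(tree$merge))
  get_cluster <- function(ref) {
    if (ref < 0) clusters[[-ref]] else node_cluster[[ref]]
  }
  for (m in seq_len(nrow(tree$merge))) {
    a <- get_cluster(tree$merge[m, 1])
    b <- get_cluster(tree$merge[m, 2])
    merged <- align_clusters(a$cols, b$cols, posmat, a$members, b$members,
                             gap_open, gap_ext)
    node_cluster[[m]] <- list(cols = merged,
                              members = sort(c(a$members, b$members)))
  }
  final <- node_cluster[[nrow(tree$merge)]]
  list(msa = colmat_to_msa(final$cols, x$names,
                           vapply(structures, `[[`, "", "sequence")),
       tree = tree, scores = scores)
}

#' Iterative progressive refinement of an MSA
#'
#' Runs up to `max_steps` progressive passes. Each pass superimposes all
#' structures on the current MSA, computes the PC_div matrix, builds the
#' average-linkage guide tree and re-aligns clusters leaf-to-root with the
#' PC_sim-based profile score. Stops early when the average pairwise PC_sim
#' converges (change < 1e-6) or an MSA repeats (cycle). Returns the MSA with
#' the largest average PC_sim over all iterations including the seed.
#'
#' @param structures list of [protein_structure()] objects.
#' @param seed_msa starting [msa()] (e.g. from [clique_msa()]).
#' @param max_steps maximum progressive passes (default 7).
#' @param bonus aligned-pair bonus in the profile score (default 0.1).
#' @param gap_open,gap_ext affine gap parameters (defaults 0.35 / 0.05).
#' @return list of class `progressive_result`: `msa` (the selected one),
#'   `avg_pc` (its average PC_sim), `log` (data.frame per iteration:
#'   iteration, avg_pc, selected), `msas`, `trees`, `superposition` (the
#'   consensus superposition of the selected MSA), `pair_scores` (pair table
#'   of the selected MSA).
#' @export
run_progressive <- function(structures, seed_msa, max_steps = 7,
                            bonus = 0.1, gap_open = 0.35, gap_ext = 0.05) {
  avg_pc_of <- function(x) mean(msa_pair_scores(x, structures)$PC)
  msas <- list(seed_msa)
  avgs <- avg_pc_of(seed_msa)
  hashes <- paste(seed_msa$rows, collapse = "\n")
  trees <- list()
  cur <- seed_msa
  for (step in seq_len(max_steps)) {
    msup <- multiple_superposition(cur, structures)
    pass <- progressive_pass(cur, structures, msup, bonus, gap_open, gap_ext)
    cand <- pass$msa
    trees[[length(trees) + 1]] <- pass$tree
    h <- paste(cand$rows, collapse = "\n")
    a <- avg_pc_of(cand)
    msas <- c(msas, list(cand))
    avgs <- c(avgs, a)
    if (h %in% hashes) break
    hashes <- c(hashes, h)
    if (abs(a - avgs[length(avgs) - 1]) < 1e-6) break
    cur <- cand
  }
  best <- which.max(avgs)
  sel <- msas[[best]]
  msup <- multiple_superposition(sel, structures)
  structure(list(
    msa = sel, avg_pc = avgs[best],
    log = data.frame(iteration = seq_along(avgs) - 1, avg_pc = avgs,
                     selected = seq_along(avgs) == best),
    msas = msas, trees = trees, superposition = msup,
    pair_scores = msa_pair_scores(sel, structures)
  ), class = "progressive_result")
}
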