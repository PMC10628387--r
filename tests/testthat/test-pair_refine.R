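# Gap relocation, neighbor maps, frame refinement and de novo alignment.

test_that("a gap inside a secondary-structure element moves to the nearer end", {
  # protein 2 carries a 6-residue helix at positions 3..8; protein 1 has a
  # deletion aligned to position 4 (one residue into the helix)
  s2 <- make_scaffold(12, "helix", id = "s2")
  ss2 <- paste0("CC", strrep("H", 6), "CCCC")  # helix 3..8
  s2$sstruct <- ss2
  s1 <- toy_structure("s1", s2$calpha[-4, , drop = FALSE],
                      sequence = substr(paste(rep("A", 12), collapse = ""), 1, 11),
                      sstruct = paste0("CC", strrep("H", 5), "CCCC"))
  pairs <- cbind(c(1:3, NA, 4:11), 1:12)
  pa <- pairwise_alignment("s1", "s2", pairs)
  rr <- ss_realign(pa, s1, s2)
  gap_at <- which(is.na(rr$modified$pairs[, 1]))
  # left shift 1 vs right shift 4: the gap moves to the N-terminal flank
  expect_equal(unname(rr$modified$pairs[gap_at, 2]), 3)
  # here the input alignment is structurally perfect, so it is kept
  expect_identical(rr$refined$pairs, pa$pairs)
  expect_s3_class(rr$refined, "pairwise_alignment")
})

test_that("ss_realign is a no-op without gaps inside elements and reports maxima", {
  f <- evolve_family(family_spec(n = 2, L = 40, sub_rate = 0.3,
                                 indel_rate = 0, sigma = 0.4, seed = 61))
  pa <- pa_from_msa(f$truth_msa, 1, 2)
  rr <- ss_realign(pa, f$structures[[1]], f$structures[[2]])
  expect_identical(rr$refined$pairs, pa$pairs)   # gapless input
  # selection rule on randomized gapped toys
  set.seed(62)
  for (rep in 1:3) {
    f2 <- evolve_family(family_spec(n = 2, L = 40, sub_rate = 0.3,
                                    indel_rate = 2, sigma = 0.4,
                                    seed = 70 + rep))
    pa2 <- pa_from_msa(f2$truth_msa, 1, 2)
    r2 <- ss_realign(pa2, f2$structures[[1]], f2$structures[[2]])
    expect_gte(r2$scores_out$SI, r2$scores_in$SI)
    expect_gte(r2$scores_out$TM, r2$scores_in$TM - 1e-9)
  }
})

test_that("nearest map under TM is the identity for a rigid copy", {
  s <- make_scaffold(20, "mixed")
  tr <- random_rigid()
  s2 <- transform_structure(s, tr$rotation, tr$translation)
  nm <- nearest_map(identity_pa("a", "b", 20), s, s2, "TM")
  expect_equal(nm$n1, 1:20)
  expect_equal(nm$n2, 1:20)
  expect_equal(nrow(nm$double), 20)
})

test_that("nearest map under CO maximizes the brute-force shared-contact count", {
  set.seed(41)
  f <- evolve_family(family_spec(n = 2, L = 30, sub_rate = 0.2,
                                 indel_rate = 0, sigma = 0.5, seed = 91))
  s1 <- f$structures[[1]]; s2 <- f$structures[[2]]
  pa <- pa_from_msa(f$truth_msa, 1, 2)
  nm <- nearest_map(pa, s1, s2, "CO")
  al <- pa_aligned(pa)
  amap <- rep(NA_integer_, s1$L)
  amap[al[, 1]] <- al[, 2]
  for (i in seq_len(s1$L)) {
    cnt <- vapply(seq_len(s2$L), function(j) {
      ks <- which(s1$contacts[i, ] == 1 & !is.na(amap))
      sum(s2$contacts[amap[ks], j])
    }, numeric(1))
    if (max(cnt) == 0) expect_true(is.na(nm$n1[i]))
    else expect_equal(cnt[nm$n1[i]], max(cnt))
  }
  # double-match symmetry: identical pair set from either side
  nm_swap <- nearest_map(swap_pa(pa), s2, s1, "CO")
  expect_setequal(paste(nm$double[, 1], nm$double[, 2]),
                  paste(nm_swap$double[, 2], nm_swap$double[, 1]))
})

test_that("frame refinement recovers a planted misalignment on a rigid copy", {
  s <- make_scaffold(30, "mixed")
  tr <- random_rigid()
  s2 <- transform_structure(s, tr$rotation, tr$translation)
  # plant a 2-column register error in the middle
  matches <- cbind(1:28, c(1:12, 15:30))  # skips 13,14 on one side
  pa_bad <- pa_from_matches("a", "b", matches[-(13:14), ], 30, 30)
  rr <- refine_pa(pa_bad, s, s2, target = "TM")
  sc_bad <- score_pa(pa_bad, s, s2)
  expect_gt(rr$scores_out$TM, sc_bad$TM)
  expect_equal(pa_aligned(rr$refined), pa_aligned(identity_pa("a", "b", 30)),
               ignore_attr = TRUE)
})

test_that("refinement is a fixed point on an already optimal alignment", {
  s <- make_scaffold(25, "mixed")
  tr <- random_rigid()
  s2 <- transform_structure(s, tr$rotation, tr$translation)
  pa <- identity_pa("a", "b", 25)
  for (tg in c("TM", "CO", "PC")) {
    rr <- refine_pa(pa, s, s2, tg)
    expect_identical(rr$refined$pairs, pa$pairs)
    expect_lte(rr$iterations, 2)
  }
})

test_that("refinement keeps the better alignment and outputs stay monotone", {
  set.seed(51)
  for (rep in 1:3) {
    f <- evolve_family(family_spec(n = 2, L = 40, sub_rate = 0.4,
                                   indel_rate = 1.5, sigma = 0.8,
                                   seed = 200 + rep))
    s1 <- f$structures[[1]]; s2 <- f$structures[[2]]
    pa <- random_pa(s1$id, s2$id, s1$L, s2$L, p_match = 0.8)
    for (tg in c("TM", "CO", "PC")) {
      rr <- refine_pa(pa, s1, s2, tg)
      tin <- pcali:::target_score(rr$scores_in, tg)
      tout <- pcali:::target_score(rr$scores_out, tg)
      expect_gte(tout, tin)
      expect_silent(pcali:::validate_pa(rr$refined$pairs))
      # idempotence applies once the inner loop has converged
      if (rr$iterations < 5) {
        rr2 <- refine_pa(rr$refined, s1, s2, tg)
        expect_identical(rr2$refined$pairs, rr$refined$pairs)
      }
    }
  }
})

test_that("de novo alignment of identical structures is the gapless identity", {
  f <- evolve_family(family_spec(n = 2, L = 30, sub_rate = 0, indel_rate = 0,
                                 sigma = 0, seed = 3))
  pa <- denovo_pa(f$structures[[1]], f$structures[[2]])
  expect_equal(pa$pairs, cbind(i = 1:30, j = 1:30), ignore_attr = TRUE)
})

test_that("de novo alignment places a single block gap for a clean deletion", {
  s <- make_scaffold(30, "mixed", sequence = paste(
    sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 30, replace = TRUE),
    collapse = ""))
  keep <- setdiff(1:30, 14:16)
  s2 <- protein_structure("del", substring(paste(strsplit(s$sequence, "")[[1]][keep],
                                                 collapse = ""), 1),
                          s$calpha[keep, , drop = FALSE], s$atoms[keep])
  pa <- denovo_pa(s, s2)
  gaps <- which(is.na(pa$pairs[, 2]))
  expect_length(gaps, 3)
  expect_equal(diff(gaps), c(1, 1))           # one contiguous 3-column gap
  al <- pa_aligned(pa)
  expect_equal(al[, 1], keep)                 # correspondence recovered
})

test_that("de novo alignment is mirror-symmetric", {
  f <- evolve_family(family_spec(n = 2, L = 35, sub_rate = 0.3,
                                 indel_rate = 1, sigma = 0.5, seed = 12))
  a <- denovo_pa(f$structures[[1]], f$structures[[2]])
  b <- denovo_pa(f$structures[[2]], f$structures[[1]])
  expect_equal(pa_aligned(a), pa_aligned(swap_pa(b)), ignore_attr = TRUE)
})

test_that("contact vector similarity is bounded and zero for empty degrees", {
  s <- make_scaffold(20, "mixed")
  cvs <- contact_vector_similarity(s$contacts, s$contacts)
  expect_true(all(cvs >= 0 & cvs <= 1))
  deg <- rowSums(s$contacts)
  expect_true(all(diag(cvs)[deg > 0] == 1))
  expect_true(all(diag(cvs)[deg == 0] == 0))
  empty <- matrix(0L, 5, 5)
  expect_true(all(contact_vector_similarity(empty, empty) == 0))
})
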