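# Similarity measures: ali, SI, TM, CO, PC and the covariance PCA.

test_that("aligned fraction is L_ali over the longer length", {
  expect_equal(aligned_fraction(identity_pa("a", "b", 10), 10, 10), 1)
  pa <- pairwise_alignment("a", "b",
                           rbind(cbind(1:8, 1:8), c(9, NA), c(10, NA)))
  expect_equal(aligned_fraction(pa, 10, 8), 0.8)
  empty <- pairwise_alignment("a", "b", cbind(1:3, NA))
  expect_equal(aligned_fraction(empty, 3, 5), 0)
})

test_that("sequence identity scores aligned columns only", {
  pa <- identity_pa("a", "b", 4)
  expect_equal(sequence_identity(pa, "ACDE", "ACDE"), 1)
  pa2 <- identity_pa("a", "b", 2)
  expect_equal(sequence_identity(pa2, "AC", "AD"), 0.5)
  # flanking gap columns leave SI unchanged (indels are not scored)
  pa3 <- pairwise_alignment("a", "b",
                            rbind(c(NA, 1), c(1, 2), c(2, 3), c(3, NA)))
  expect_equal(sequence_identity(pa3, "ACX", "ZAC"), 1)
  expect_error(sequence_identity(identity_pa("a", "b", 5), "AC", "ACDEF"),
               "out of")
})

test_that("d0 follows the printed formula with a floor for short alignments", {
  expect_equal(tm_d0(100), 1.24 * (85)^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(100), 3.652, tolerance = 1e-3)
  expect_equal(tm_d0(4), 0.5)   # formula would be negative
  expect_equal(tm_d0(21), 0.5)  # formula ~0.46, clamped
})

test_that("TM-score algebra: perfect superposition and the d0 half point", {
  expect_equal(tm_score(rep(0, 10), L_norm = 10), 1)
  d0 <- tm_d0(50)
  expect_equal(tm_score(d0, L_norm = 50), 0.5 / 50)
})

test_that("superposition of a rigid copy recovers the transform exactly", {
  s <- make_scaffold(20, "mixed")
  tr <- random_rigid()
  y <- apply_transform(s$calpha, tr$rotation, tr$translation)
  sup <- optimal_superposition(identity_pa("a", "b", 20), s$calpha, y)
  expect_lt(max(sup$distances), 1e-6)
  expect_equal(sup$tm, 1, tolerance = 1e-9)
  expect_lt(max(abs(t(sup$rotation) %*% sup$rotation - diag(3))), 1e-9)
})

test_that("iterative superposition beats one-pass least squares on a displaced loop", {
  set.seed(21)
  s <- make_scaffold(40, "helix")
  x <- s$calpha
  y <- x
  y[18:23, ] <- y[18:23, ] + matrix(stats::runif(18, 6, 9), 6, 3) # displaced loop
  tr <- random_rigid()
  y <- apply_transform(y, tr$rotation, tr$translation)
  sup <- optimal_superposition(identity_pa("a", "b", 40), x, y)
  k <- pcali:::kabsch(x, y)
  d_k <- sqrt(rowSums((apply_transform(x, k$rotation, k$translation) - y)^2))
  tm_k <- tm_score(d_k, L_norm = 40)
  expect_gte(sup$tm, tm_k)
  expect_gt(sup$tm, tm_k + 0.01) # strictly better here, not just equal
})

test_that("contact overlap matches hand enumeration and handles no contacts", {
  L <- 8
  C1 <- matrix(0L, L, L); C2 <- matrix(0L, L, L)
  C1[1, 6] <- C1[6, 1] <- 1L
  C1[2, 7] <- C1[7, 2] <- 1L
  C2[1, 6] <- C2[6, 1] <- 1L
  pa <- identity_pa("a", "b", L)
  expect_equal(contact_overlap(pa, C1, C2), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(contact_overlap(pa, C1, C1), 1)
  expect_warning(v <- contact_overlap(pa, C1, matrix(0L, L, L)), "zero contacts")
  expect_true(is.na(v))
})

test_that("PC similarity is the fixed weighted combination", {
  expect_equal(pc_sim(1, 1, 1, 1), 1, tolerance = 1e-12)
  expect_equal(pc_sim(0, 0, 0, 0), 0)
  expect_equal(pc_sim(0.5, 0.2, 0.6, 0.55),
               (0.84 * 0.5 + 0.79 * 0.2 + 0.95 * 0.6 + 0.95 * 0.55) / 3.53)
  expect_equal(pc_sim(0.5, 0.2, 0.6, 0.55), 0.4732, tolerance = 1e-4)
  expect_error(pc_sim(1.2, 0, 0, 0), "0, 1")
  # monotone nondecreasing in each argument
  set.seed(8)
  for (k in 1:20) {
    v <- stats::runif(4)
    j <- sample(4, 1)
    v2 <- v
    v2[j] <- min(1, v[j] + stats::runif(1, 0, 1 - v[j]))
    expect_gte(do.call(pc_sim, as.list(v2)), do.call(pc_sim, as.list(v)))
  }
})

test_that("all five similarities are symmetric under swapping the proteins", {
  set.seed(77)
  for (rep in 1:3) {
    f <- evolve_family(family_spec(n = 2, L = 30, sub_rate = 0.4,
                                   indel_rate = 1, sigma = 0.6,
                                   seed = 500 + rep))
    s1 <- f$structures[[1]]; s2 <- f$structures[[2]]
    pa <- pa_from_msa(f$truth_msa, 1, 2)
    sc12 <- score_pa(pa, s1, s2)
    sc21 <- score_pa(swap_pa(pa), s2, s1)
    expect_equal(sc12$ali, sc21$ali)
    expect_equal(sc12$SI, sc21$SI)
    expect_equal(sc12$CO, sc21$CO)
    expect_equal(sc12$TM, sc21$TM, tolerance = 1e-6)
    expect_equal(sc12$PC, sc21$PC, tolerance = 1e-6)
  }
})

test_that("self-alignment scores are all one", {
  s <- make_scaffold(25, "mixed")
  sc <- score_pa(identity_pa(s$id, s$id, s$L), s, s)
  expect_equal(unlist(sc[c("ali", "SI", "TM", "CO", "PC")]),
               c(ali = 1, SI = 1, TM = 1, CO = 1, PC = 1), tolerance = 1e-9)
})

test_that("covariance PCA recovers degenerate and planted leading directions", {
  v <- stats::runif(20)
  tab <- cbind(v, v, v, v)
  p <- pca_loads(tab)
  expect_equal(abs(p$loads), rep(0.5, 4), tolerance = 1e-9)
  expect_equal(p$variance_fractions[1], 1)
  # two independent columns with equal variance, two constant columns
  a <- c(1, 1, -1, -1); b <- c(1, -1, 1, -1)
  p2 <- pca_loads(cbind(a, b, 0.5, 0.5))
  expect_equal(p2$variance_fractions[1:2], c(0.5, 0.5), tolerance = 1e-12)
  # planted leading eigenvector
  set.seed(13)
  w <- c(0.84, 0.79, 0.95, 0.95) / sqrt(sum(c(0.84, 0.79, 0.95, 0.95)^2))
  z <- stats::rnorm(4000)
  noise <- matrix(stats::rnorm(16000, sd = 0.15), 4000, 4)
  tab3 <- z %*% t(w) + noise
  p3 <- pca_loads(tab3)
  expect_lt(max(abs(p3$loads - w)), 0.02)
  expect_error(pca_loads(matrix(1, 10, 4)), "degenerate")
})
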