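# Residue graph, clique enumeration and MSA assembly.

test_that("the graph of consistent identity alignments is a union of triangles", {
  ids <- c("A", "B", "C")
  lens <- stats::setNames(c(2, 2, 2), ids)
  pas <- list(identity_pa("A", "B", 2), identity_pa("A", "C", 2),
              identity_pa("B", "C", 2))
  g <- build_graph(pas, ids, lens)
  expect_equal(g$n_nodes, 6)
  expect_equal(sum(lengths(g$adj)) / 2, 6)
  cc <- clustering_coefficients(g)
  expect_equal(cc, rep(1L, 6))   # every node closes one triangle
  # single PA -> matching; empty PA -> no edges
  g1 <- build_graph(list(identity_pa("A", "B", 2)), ids, lens)
  expect_equal(lengths(g1$adj), c(1, 1, 1, 1, 0, 0))
  g0 <- build_graph(list(pairwise_alignment("A", "B", cbind(1:2, NA))),
                    ids, lens)
  expect_equal(sum(lengths(g0$adj)), 0)
  expect_error(build_graph(c(pas, list(identity_pa("A", "B", 2))), ids, lens),
               "duplicate")
})

test_that("clustering coefficients match a brute-force recount on random graphs", {
  set.seed(17)
  for (rep in 1:3) {
    rs <- random_pa_set(4, 6, p_match = 0.6)
    g <- build_graph(rs$pas, rs$ids, rs$lengths)
    cc <- clustering_coefficients(g)
    brute <- vapply(seq_len(g$n_nodes), function(v) {
      nb <- g$adj[[v]]
      if (length(nb) < 2) return(0L)
      cnt <- 0L
      for (a in seq_along(nb)) for (b in seq_along(nb)) {
        if (b > a && nb[b] %in% g$adj[[nb[a]]]) cnt <- cnt + 1L
      }
      cnt
    }, integer(1))
    expect_equal(cc, brute)
  }
})

test_that("per-node cliques match exhaustive enumeration on small graphs", {
  ids <- c("A", "B", "C")
  lens <- stats::setNames(c(2, 2, 2), ids)
  pas <- list(identity_pa("A", "B", 2), identity_pa("A", "C", 2),
              identity_pa("B", "C", 2))
  g <- build_graph(pas, ids, lens)
  cl <- cliques_for_node(g, 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]], c(1, 3, 5))   # residue 1 of each protein
  # two mutually non-adjacent neighbors -> two cliques of size 2
  g2 <- build_graph(list(identity_pa("A", "B", 2), identity_pa("A", "C", 2)),
                    ids, lens)
  cl2 <- cliques_for_node(g2, 1)
  expect_length(cl2, 2)
  expect_true(all(lengths(cl2) == 2))
  # random PA graphs vs igraph maximal cliques
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:4) {
    rs <- random_pa_set(sample(3:6, 1), sample(4:10, 1), p_match = 0.6)
    g3 <- build_graph(rs$pas, rs$ids, rs$lengths)
    for (v in sample(which(lengths(g3$adj) > 0), 5)) {
      mine <- cliques_for_node(g3, v, cap = 100)
      truth <- igraph_cliques_for_node(g3, v)
      if (length(truth) <= 100) {
        expect_equal(max(lengths(mine)), max(lengths(truth)))
      }
    }
  }
})

test_that("global enumeration covers consistent alignments and deduplicates", {
  ids <- c("A", "B", "C")
  lens <- stats::setNames(c(4, 4, 4), ids)
  pas <- list(identity_pa("A", "B", 4), identity_pa("A", "C", 4),
              identity_pa("B", "C", 4))
  g <- build_graph(pas, ids, lens)
  cl <- enumerate_all(g)
  keys <- vapply(cl, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  full <- cl[lengths(cl) == 3]
  expect_length(full, 4)   # one triangle per column
})

test_that("assembly reconstructs consistent inputs and resolves conflicts by size", {
  f <- evolve_family(family_spec(n = 3, L = 20, sub_rate = 0.2,
                                 indel_rate = 0, sigma = 0.3, seed = 301))
  pas <- list(pa_from_msa(f$truth_msa, 1, 2), pa_from_msa(f$truth_msa, 1, 3),
              pa_from_msa(f$truth_msa, 2, 3))
  for (k in seq_along(pas)) {
    pas[[k]]$id1 <- f$truth_msa$names[c(1, 1, 2)[k]]
    pas[[k]]$id2 <- f$truth_msa$names[c(2, 3, 3)[k]]
  }
  out <- clique_msa(pas, f$structures)
  expect_equal(sum_of_pairs(out, f$truth_msa)$sum_of_pairs, 1)
  # hand-constructed conflict: a 3-clique and an incompatible 2-clique
  ids <- c("A", "B", "C")
  lens <- stats::setNames(c(2, 2, 2), ids)
  pas2 <- list(
    identity_pa("A", "B", 2),                              # A1-B1, A2-B2
    pairwise_alignment("A", "C", rbind(c(1, 1), c(2, NA), c(NA, 2))),
    pairwise_alignment("B", "C", rbind(c(1, 1), c(2, 2)))
  )
  g <- build_graph(pas2, ids, lens)
  cl <- enumerate_all(g)
  seqs <- c("AC", "AC", "AC")
  out2 <- assemble_msa(cl, g, seqs)
  # the triangle A1-B1-C1 must be one column; B2-C2 consistent; A2 joins B2
  cm <- pcali:::msa_to_colmat(out2)
  col1 <- which(!is.na(cm[, 1]) & cm[, 1] == 1)
  expect_equal(cm[col1, ], c(1, 1, 1), ignore_attr = TRUE)
})

test_that("every residue appears exactly once and in order after assembly", {
  set.seed(19)
  for (rep in 1:3) {
    f <- evolve_family(family_spec(n = 4, L = 25, sub_rate = 0.35,
                                   indel_rate = 1.5, sigma = 0.6,
                                   seed = 400 + rep))
    cmb <- utils::combn(4, 2)
    pas <- lapply(seq_len(ncol(cmb)), function(k) {
      pa <- pa_from_msa(f$truth_msa, cmb[1, k], cmb[2, k])
      pa
    })
    out <- clique_msa(pas, f$structures)
    expect_valid_msa(out, f$structures)
  }
})

test_that("greedy clique assembly is near the optimal consistent subset on toys", {
  skip_if_not_installed("igraph")
  # oracle: exhaustive search over consistent subsets of maximal cliques
  best_subset_size <- function(cliques, g) {
    n <- length(cliques)
    best <- 0
    cols <- lapply(cliques, function(cl) pcali:::col_vec(g, cl))
    recurse <- function(k, chosen, used, total) {
      if (k > n) { best <<- max(best, total); return() }
      # upper bound prune
      if (total + sum(lengths(cliques[k:n])) <= best) return()
      # option 1: take clique k if consistent
      cl <- cliques[[k]]
      if (!any(used[cl])) {
        ok <- all(vapply(chosen, function(ci) {
          pcali:::cols_consistent(cols[[ci]], cols[[k]])
        }, TRUE)) && pcali:::cols_acyclic(cols[c(chosen, k)])
        if (ok) {
          used2 <- used; used2[cl] <- TRUE
          recurse(k + 1, c(chosen, k), used2, total + length(cl))
        }
      }
      recurse(k + 1, chosen, used, total)
    }
    recurse(1, integer(0), logical(g$n_nodes), 0)
    best
  }
  set.seed(29)
  for (rep in 1:3) {
    rs <- random_pa_set(sample(3:5, 1), sample(5:8, 1), p_match = 0.55)
    g <- build_graph(rs$pas, rs$ids, rs$lengths)
    cl <- enumerate_all(g)
    cl <- cl[order(-lengths(cl))]
    if (length(cl) > 14) cl <- cl[1:14]  # keep the oracle tractable
    opt <- best_subset_size(cl, g)
    # greedy acceptance as in assembly
    used <- logical(g$n_nodes)
    acc <- list(); total <- 0
    for (cli in cl) {
      v <- pcali:::col_vec(g, cli)
      if (any(used[cli])) next
      if (!all(vapply(acc, function(x) pcali:::cols_consistent(x, v), TRUE))) next
      if (!pcali:::cols_acyclic(c(acc, list(v)))) next
      acc <- c(acc, list(v)); used[cli] <- TRUE; total <- total + length(cli)
    }
    expect_gte(total, 0.9 * opt)
  }
})
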