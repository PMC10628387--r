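# Shared helpers: tiny structures built in code, random alignments, and the
# independent oracles used by the equivalence tests.

# toy structure from explicit C-alpha coordinates (atoms = CA only unless given)
toy_structure <- function(id, calpha, sequence = NULL, atoms = NULL,
                          sstruct = NULL, contacts = NULL) {
  L <- nrow(calpha)
  protein_structure(
    id = id, sequence = sequence %||% strrep("A", L), calpha = calpha,
    atoms = atoms, contacts = contacts,
    sstruct = sstruct %||% strrep("C", L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ideal extended-strand C-alpha trace (3.3 A rise, small pleat)
strand_coords_test <- function(L) {
  cbind(seq_len(L) * 3.3, 0.5 * (-1)^(seq_len(L)), 0)
}

# random monotone pairwise alignment over lengths L1, L2 (seeded by caller)
random_pa <- function(id1, id2, L1, L2, p_match = 0.7) {
  i <- 1L; j <- 1L
  pairs <- matrix(NA_integer_, 0, 2)
  while (i <= L1 || j <= L2) {
    r <- stats::runif(1)
    if (i <= L1 && j <= L2 && r < p_match) {
      pairs <- rbind(pairs, c(i, j)); i <- i + 1L; j <- j + 1L
    } else if (i <= L1 && (j > L2 || r < p_match + (1 - p_match) / 2)) {
      pairs <- rbind(pairs, c(i, NA)); i <- i + 1L
    } else {
      pairs <- rbind(pairs, c(NA, j)); j <- j + 1L
    }
  }
  pairwise_alignment(id1, id2, pairs)
}

# swap the two sides of a pairwise alignment
swap_pa <- function(pa) {
  pairwise_alignment(pa$id2, pa$id1, pa$pairs[, c(2, 1)])
}

# brute-force contact matrix: all-pairs scan over every atom pair
brute_contacts <- function(atoms, cutoff = 4.5, min_sep = 3) {
  L <- length(atoms)
  out <- matrix(0L, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (abs(i - j) < min_sep) next
    for (a in seq_len(nrow(atoms[[i]]))) for (b in seq_len(nrow(atoms[[j]]))) {
      if (sqrt(sum((atoms[[i]][a, ] - atoms[[j]][b, ])^2)) < cutoff) {
        out[i, j] <- 1L
      }
    }
  }
  out
}

# rotation matrix from Euler-style angles (independent of package internals)
euler_rot <- function(a, b, c) {
  rz <- function(t_) matrix(c(cos(t_), sin(t_), 0, -sin(t_), cos(t_), 0,
                              0, 0, 1), 3, 3)
  ry <- function(t_) matrix(c(cos(t_), 0, -sin(t_), 0, 1, 0,
                              sin(t_), 0, cos(t_)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

random_rigid <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::runif(3, -15, 15))
}

transform_structure <- function(s, rot, trans) {
  protein_structure(
    id = s$id, sequence = s$sequence,
    calpha = apply_transform(s$calpha, rot, trans),
    atoms = lapply(s$atoms, function(a) apply_transform(a, rot, trans)),
    contacts = s$contacts, sstruct = s$sstruct
  )
}

# brute-force TM maximization over rotations: Euler grid + Nelder-Mead
# refinement with one restart from every grid point
brute_tm <- function(x, y, L_norm) {
  d0 <- tm_d0(L_norm)
  cx <- colMeans(x); cy <- colMeans(y)
  obj <- function(par) {
    r <- euler_rot(par[1], par[2], par[3])
    d <- sqrt(rowSums((sweep(x %*% t(r), 2, par[4:6], `+`) - y)^2))
    sum(1 / (1 + (d / d0)^2)) / L_norm
  }
  best <- -Inf
  for (a in seq(0, 2 * pi, length.out = 9)[-9]) {
    for (b in seq(0, pi, length.out = 5)) {
      for (cc in seq(0, 2 * pi, length.out = 9)[-9]) {
        tr0 <- cy - as.numeric(euler_rot(a, b, cc) %*% cx)
        o <- stats::optim(c(a, b, cc, tr0), obj, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 1200,
                                         reltol = 1e-14))
        o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 1200,
                                         reltol = 1e-14))
        if (o$value > best) best <- o$value
      }
    }
  }
  best
}

# exhaustive column correspondence for column_overlap: best one-to-one
# matching of A columns to B columns by total shared residues (<= 8 columns)
brute_column_overlap <- function(msaA, msaB) {
  cmA <- pcali:::msa_to_colmat(msaA)
  cmB <- pcali:::msa_to_colmat(msaB)
  keys <- function(cm) lapply(seq_len(nrow(cm)), function(a) {
    v <- cm[a, ]; paste(which(!is.na(v)), v[!is.na(v)])
  })
  kA <- keys(cmA); kB <- keys(cmB)
  nA <- length(kA); nB <- length(kB)
  shared <- matrix(0L, nA, nB)
  for (a in seq_len(nA)) for (b in seq_len(nB)) {
    shared[a, b] <- length(intersect(kA[[a]], kB[[b]]))
  }
  total <- sum(!is.na(cmA))
  k <- min(nA, nB)
  best <- 0
  # assign each A column to a distinct B column (or none): permutations
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  if (nA <= nB) {
    for (p in perms(seq_len(nB))) {
      s <- sum(shared[cbind(seq_len(nA), p[seq_len(nA)])])
      best <- max(best, s)
    }
  } else {
    for (p in perms(seq_len(nA))) {
      s <- sum(shared[cbind(p[seq_len(nB)], seq_len(nB))])
      best <- max(best, s)
    }
  }
  best / total
}

# random PA graph: consistent-by-construction random pairwise alignments
# between n proteins of length L (possibly with noise edges via shuffling)
random_pa_set <- function(n, L, p_match = 0.7) {
  ids <- sprintf("T%d", seq_len(n))
  pas <- list()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    pas[[length(pas) + 1]] <- random_pa(ids[a], ids[b], L, L, p_match)
  }
  list(ids = ids, lengths = stats::setNames(rep(L, n), ids), pas = pas)
}

# igraph-based exhaustive maximal cliques containing a node
igraph_cliques_for_node <- function(g, v) {
  el <- do.call(rbind, lapply(seq_len(g$n_nodes), function(u) {
    nb <- g$adj[[u]]
    nb <- nb[nb > u]
    if (length(nb)) cbind(u, nb) else NULL
  }))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, g$n_nodes - igraph::vcount(ig)))
  cl <- igraph::max_cliques(ig)
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  cl[vapply(cl, function(x) v %in% x, TRUE)]
}

expect_valid_msa <- function(x, structures) {
  ids <- vapply(structures, `[[`, "", "id")
  expect_setequal(x$names, ids)
  expect_length(unique(nchar(x$rows)), 1)
  for (k in seq_along(ids)) {
    s <- structures[[match(x$names[k], ids)]]
    expect_identical(gsub("-", "", x$rows[k]), s$sequence)
  }
  m <- do.call(rbind, strsplit(x$rows, ""))
  expect_true(all(colSums(m != "-") > 0))
}
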