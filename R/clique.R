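# Clique-based multiple alignment: residues of all proteins are nodes of a
# graph whose edges join residues aligned in some pairwise alignment; when
# the alignments are mutually consistent, MSA columns are maximal cliques.

#' Build the residue graph of a set of pairwise alignments
#'
#' Nodes are (protein, residue) pairs of the `n` proteins; undirected edges
#' connect residues aligned in a pairwise alignment. Each unordered protein
#' pair may contribute at most one alignment, so each residue has at most one
#' link into each other protein (degree <= n - 1).
#'
#' @param pas list of [pairwise_alignment()] objects whose id1/id2 name the
#'   proteins.
#' @param ids ordered protein ids.
#' @param lengths protein lengths, named by `ids` or in the same order.
#' @return object of class `pa_graph`: `ids`, `lengths`, `offset`, `n_nodes`,
#'   adjacency list `adj` (sorted integer vectors).
#' @export
build_graph <- function(pas, ids, lengths) {
  if (is.null(names(lengths))) names(lengths) <- ids
  lengths <- lengths[ids]
  offset <- c(0, cumsum(lengths))[seq_along(ids)]
  names(offset) <- ids
  n_nodes <- sum(lengths)
  adj <- vector("list", n_nodes)
  seen <- character(0)
  for (pa in pas) {
    key <- paste(sort(c(pa$id1, pa$id2)), collapse = "|")
    if (key %in% seen) stop("duplicate pairwise alignment for pair ", key)
    seen <- c(seen, key)
    al <- pa_aligned(pa)
    if (nrow(al) == 0) next
    u <- offset[pa$id1] + al[, 1]
    v <- offset[pa$id2] + al[, 2]
    for (k in seq_along(u)) {
      adj[[u[k]]] <- c(adj[[u[k]]], v[k])
      adj[[v[k]]] <- c(adj[[v[k]]], u[k])
    }
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(ids = ids, lengths = lengths, offset = offset,
                 n_nodes = n_nodes, adj = adj),
            class = "pa_graph")
}

#' Protein and residue of graph nodes
#' @param g a `pa_graph`.
#' @param v node indices.
#' @return data.frame with columns protein (index) and residue.
#' @export
node_info <- function(g, v) {
  p <- findInterval(v - 1, c(g$offset, g$n_nodes), rightmost.closed = FALSE)
  data.frame(protein = p, residue = as.integer(v - g$offset[p]))
}

graph_has_edge <- function(g, u, v) v %in% g$adj[[u]]

#' Clustering coefficients (triangle counts) of all nodes
#'
#' For each node, the number of unordered pairs of its neighbors that are
#' themselves neighbors. Used to rank seeds for clique enumeration.
#'
#' @param g a `pa_graph`.
#' @return integer vector over nodes.
#' @export
clustering_coefficients <- function(g) {
  vapply(seq_len(g$n_nodes), function(v) {
    nb <- g$adj[[v]]
    if (length(nb) < 2) return(0L)
    cnt <- 0L
    for (a in seq_len(length(nb) - 1)) {
      cnt <- cnt + sum(g$adj[[nb[a]]] %in% nb[(a + 1):length(nb)])
    }
    cnt
  }, integer(1))
}

#' Maximal cliques through one node, by incremental growth
#'
#' Processes the node's neighbors in order: the first neighbor forms the
#' first clique with the node; each subsequent neighbor joins every existing
#' clique whose members it is fully linked to, and otherwise seeds a new
#' clique containing the node, the neighbor, and previously seen common
#' neighbors that keep the set fully connected. After each step only the
#' `cap` largest cliques are kept (ties keep the earlier-created). At
#' exhaustion the stored cliques that are not subsets of another are
#' returned.
#'
#' @param g a `pa_graph`.
#' @param v node index.
#' @param cap maximum number of cliques kept per step (default 100).
#' @return list of sorted integer vectors (each containing `v`).
#' @export
cliques_for_node <- function(g, v, cap = 100) {
  nb <- g$adj[[v]]
  if (length(nb) == 0) return(list())
  cliques <- list(sort(c(v, nb[1])))
  for (s in seq_along(nb)[-1]) {
    ls <- nb[s]
    joined <- FALSE
    for (ci in seq_along(cliques)) {
      others <- setdiff(cliques[[ci]], v)
      if (all(vapply(others, function(u) graph_has_edge(g, ls, u), TRUE))) {
        cliques[[ci]] <- sort(c(cliques[[ci]], ls))
        joined <- TRUE
      }
    }
    if (!joined) {
      new <- c(v, ls)
      common <- intersect(nb[seq_len(s - 1)], g$adj[[ls]])
      for (u in common) {
        if (all(vapply(setdiff(new, v), function(w) graph_has_edge(g, u, w),
                       TRUE))) {
          new <- c(new, u)
        }
      }
      cliques <- c(cliques, list(sort(new)))
    }
    cliques <- unique(cliques)
    if (length(cliques) > cap) {
      ord <- order(-vapply(cliques, length, integer(1)), seq_along(cliques))
      cliques <- cliques[sort(ord[seq_len(cap)])]
    }
  }
  cliques <- unique(cliques)
  # drop cliques that are subsets of another stored clique
  sizes <- vapply(cliques, length, integer(1))
  keep <- vapply(seq_along(cliques), function(a) {
    !any(vapply(seq_along(cliques), function(b) {
      b != a && sizes[b] >= sizes[a] && all(cliques[[a]] %in% cliques[[b]]) &&
        !(sizes[b] == sizes[a] && b > a)
    }, TRUE))
  }, TRUE)
  cliques[keep]
}

#' Enumerate candidate MSA columns over all nodes
#'
#' Nodes are processed in descending clustering-coefficient order (ties by
#' node index). After a node's cliques are stored, each member's maximum
#' stored clique size and summed stored clique sizes are updated; nodes whose
#' stored maximum OR stored sum already exceeds n/2 (n = number of proteins)
#' are skipped as seeds. The deduplicated union of stored cliques is
#' returned.
#'
#' @param g a `pa_graph`.
#' @param cap per-step clique cap (default 100).
#' @return list of sorted integer vectors (candidate columns).
#' @export
enumerate_all <- function(g, cap = 100) {
  cc <- clustering_coefficients(g)
  ord <- order(-cc, seq_len(g$n_nodes))
  n <- length(g$ids)
  max_size <- numeric(g$n_nodes)
  sum_size <- numeric(g$n_nodes)
  store <- list()
  seen <- character(0)
  for (v in ord) {
    if (length(g$adj[[v]]) == 0) next
    if (max_size[v] > n / 2 || sum_size[v] > n / 2) next
    for (cl in cliques_for_node(g, v, cap)) {
      key <- paste(cl, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        store <- c(store, list(cl))
      }
      max_size[cl] <- pmax(max_size[cl], length(cl))
      sum_size[cl] <- sum_size[cl] + length(cl)
    }
  }
  store
}

# ---- assembly -------------------------------------------------------------

# columns represented as integer vectors res[protein], NA where absent
col_vec <- function(g, members) {
  ni <- node_info(g, members)
  v <- rep(NA_integer_, length(g$ids))
  v[ni$protein] <- ni$residue
  v
}

cols_consistent <- function(a, b) {
  sh <- which(!is.na(a) & !is.na(b))
  if (length(sh) == 0) return(TRUE)
  d <- a[sh] - b[sh]
  all(d > 0) || all(d < 0)
}

# precedence digraph over columns is acyclic?
cols_acyclic <- function(cols) {
  k <- length(cols)
  if (k <= 1) return(TRUE)
  adj <- vector("list", k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    sh <- which(!is.na(cols[[a]]) & !is.na(cols[[b]]))
    if (length(sh) == 0) next
    d <- cols[[a]][sh] - cols[[b]][sh]
    if (all(d < 0)) adj[[a]] <- c(adj[[a]], b)
    else if (all(d > 0)) adj[[b]] <- c(adj[[b]], a)
    else return(FALSE)
  }
  state <- integer(k) # 0 new, 1 active, 2 done
  ok <- TRUE
  visit <- function(u) {
    if (!ok) return()
    state[u] <<- 1L
    for (w in adj[[u]]) {
      if (state[w] == 1L) { ok <<- FALSE; return() }
      if (state[w] == 0L) visit(w)
    }
    state[u] <<- 2L
  }
  for (u in seq_len(k)) if (state[u] == 0L) visit(u)
  ok
}

order_columns <- function(cols, lengths) {
  k <- length(cols)
  if (k == 0) return(integer(0))
  adj <- vector("list", k)
  indeg <- integer(k)
  for (a in seq_len(max(k - 1, 0))) for (b in (a + 1):k) {
    sh <- which(!is.na(cols[[a]]) & !is.na(cols[[b]]))
    if (length(sh) == 0) next
    d <- cols[[a]][sh] - cols[[b]][sh]
    if (all(d < 0)) { adj[[a]] <- c(adj[[a]], b); indeg[b] <- indeg[b] + 1L }
    else if (all(d > 0)) { adj[[b]] <- c(adj[[b]], a); indeg[a] <- indeg[a] + 1L }
    else stop("inconsistent columns at ordering stage")
  }
  avgpos <- vapply(cols, function(v) {
    mean(v[!is.na(v)] / lengths[!is.na(v)])
  }, numeric(1))
  out <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail) > 0) {
    pick <- avail[order(avgpos[avail], avail)][1]
    out <- c(out, pick)
    avail <- setdiff(avail, pick)
    for (w in adj[[pick]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != k) stop("cyclic column order after assembly")
  out
}

#' Assemble an MSA from candidate clique columns
#'
#' Cliques are accepted greedily in decreasing size (ties by summed
#' clustering coefficient, then lexicographic member order) when they reuse
#' no residue of an accepted column, are pairwise order-consistent with every
#' accepted column, and keep the precedence relation acyclic. Residues in no
#' accepted column are then attached to the accepted column with the most
#' graph edges to them when the augmented column stays consistent (ties to
#' the leftmost consistent column), and otherwise seed singleton columns.
#' Columns are finally ordered topologically by the per-protein residue
#' orders (unordered ties by average normalized residue position).
#'
#' @param cliques list of candidate cliques (node-index vectors) from
#'   [enumerate_all()].
#' @param g the `pa_graph`.
#' @param sequences character vector of the protein sequences, ordered as
#'   `g$ids`.
#' @return an [msa()] containing every residue of every protein exactly once.
#' @export
assemble_msa <- function(cliques, g, sequences) {
  lengths <- g$lengths
  cc <- clustering_coefficients(g)
  if (length(cliques) > 0) {
    sizes <- vapply(cliques, length, integer(1))
    ccsum <- vapply(cliques, function(cl) sum(cc[cl]), numeric(1))
    lex <- vapply(cliques, function(cl) paste(sprintf("%06d", cl), collapse = ""), "")
    ord <- order(-sizes, -ccsum, lex)
    cliques <- cliques[ord]
  }
  used <- logical(g$n_nodes)
  acc_cols <- list()
  acc_members <- list()
  for (cl in cliques) {
    if (any(used[cl])) next
    v <- col_vec(g, cl)
    if (!all(vapply(acc_cols, function(x) cols_consistent(x, v), TRUE))) next
    if (!cols_acyclic(c(acc_cols, list(v)))) next
    acc_cols <- c(acc_cols, list(v))
    acc_members <- c(acc_members, list(cl))
    used[cl] <- TRUE
  }
  # orphan attachment
  for (v in which(!used)) {
    ni <- node_info(g, v)
    p <- ni$protein; r <- ni$residue
    edges <- vapply(acc_members, function(m) sum(g$adj[[v]] %in% m), integer(1))
    cand <- which(edges > 0 &
                    vapply(acc_cols, function(x) is.na(x[p]), TRUE))
    placed <- FALSE
    if (length(cand) > 0) {
      cand <- cand[order(-edges[cand], cand)]
      for (ci in cand) {
        aug <- acc_cols[[ci]]
        aug[p] <- r
        others <- acc_cols[-ci]
        if (all(vapply(others, function(x) cols_consistent(x, aug), TRUE)) &&
            cols_acyclic(c(others, list(aug)))) {
          acc_cols[[ci]] <- aug
          acc_members[[ci]] <- sort(c(acc_members[[ci]], v))
          used[v] <- TRUE
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      nv <- rep(NA_integer_, length(g$ids))
      nv[p] <- r
      acc_cols <- c(acc_cols, list(nv))
      acc_members <- c(acc_members, list(v))
      used[v] <- TRUE
    }
  }
  ord <- order_columns(acc_cols, lengths)
  seqs <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  rows <- vapply(seq_along(g$ids), function(p) {
    chars <- vapply(ord, function(ci) {
      r <- acc_cols[[ci]][p]
      if (is.na(r)) "-" else seqs[[p]][r]
    }, "")
    paste(chars, collapse = "")
  }, "")
  msa(g$ids, rows, drop_allgap = FALSE)
}

#' Clique-seeded MSA from pairwise alignments
#'
#' Convenience wrapper: builds the residue graph, enumerates candidate
#' cliques and assembles the seed MSA.
#'
#' @param pas list of [pairwise_alignment()] objects.
#' @param structures list of [protein_structure()] objects.
#' @param cap per-step clique cap (default 100).
#' @return an [msa()].
#' @export
clique_msa <- function(pas, structures, cap = 100) {
  ids <- vapply(structures, `[[`, "", "id")
  lengths <- vapply(structures, `[[`, integer(1), "L")
  g <- build_graph(pas, ids, lengths)
  cl <- enumerate_all(g, cap)
  assemble_msa(cl, g, vapply(structures, `[[`, "", "sequence"))
}
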