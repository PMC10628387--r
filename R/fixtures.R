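# Deterministic synthetic structure families with planted alignments.
# Scaffolds are idealized backbones with pseudo side-chain atoms (so contact
# maps are non-empty); families evolve along a planted tree with uniform-
# exchange substitutions, geometric-length indels spliced consistently into
# sequence, coordinates and the truth MSA, Gaussian coordinate jitter and a
# random rigid transform per leaf.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

helix_coords <- function(L, rise = 1.5, twist = 100, radius = 2.3,
                         origin = c(0, 0, 0), flip = FALSE) {
  th <- (seq_len(L) - 1) * twist * pi / 180
  z <- (seq_len(L) - 1) * rise
  if (flip) z <- -z
  ca <- cbind(radius * cos(th), radius * sin(th), z)
  # side-chain pseudo-atoms: CB outward/below, CG outward/above so that
  # i,i+4 heavy-atom pairs come within contact range, as in real helices
  cb <- cbind(3.3 * cos(th), 3.3 * sin(th), z - ifelse(flip, -1, 1) * 1.0)
  cg <- cbind(4.0 * cos(th), 4.0 * sin(th), z + ifelse(flip, -1, 1) * 2.5)
  list(ca = sweep(ca, 2, origin, `+`), cb = sweep(cb, 2, origin, `+`),
       cg = sweep(cg, 2, origin, `+`))
}

strand_coords <- function(L, rise = 3.3, origin = c(0, 0, 0), dir = 1) {
  x <- (seq_len(L) - 1) * rise * dir
  y <- 0.5 * (-1)^(seq_len(L))
  ca <- cbind(x, y, 0)
  cb <- cbind(x, y + 1.0 * (-1)^(seq_len(L)), 1.5 * (-1)^(seq_len(L)))
  list(ca = sweep(ca, 2, origin, `+`), cb = sweep(cb, 2, origin, `+`),
       cg = NULL)
}

#' Idealized protein scaffold
#'
#' Deterministic backbone with pseudo side-chain atoms: `helix` (rise 1.5
#' angstrom/residue, 100 degree twist, C-alpha radius 2.3 angstrom), `sheet`
#' (a two-strand antiparallel hairpin, 3.3 angstrom rise) or `mixed` (two
#' packed antiparallel helices joined by a loop). All three yield non-empty
#' contact maps.
#'
#' @param L number of residues (>= 5).
#' @param motif one of "mixed", "helix", "sheet".
#' @param id structure id.
#' @param sequence optional sequence (default poly-A).
#' @return a [protein_structure()].
#' @export
make_scaffold <- function(L, motif = c("mixed", "helix", "sheet"),
                          id = "scaffold", sequence = NULL) {
  motif <- match.arg(motif)
  stopifnot(L >= 5)
  if (motif == "helix") {
    g <- helix_coords(L)
    ca <- g$ca
    atoms <- lapply(seq_len(L), function(i) rbind(g$ca[i, ], g$cb[i, ], g$cg[i, ]))
  } else if (motif == "sheet") {
    n1 <- floor((L - 2) / 2)
    n2 <- L - 2 - n1
    s1 <- strand_coords(n1)
    xend <- (n1 - 1) * 3.3
    s2 <- strand_coords(n2, origin = c(xend, 4.8, 0), dir = -1)
    turn <- cbind(xend + c(2.2, 2.2), c(1.6, 3.2), c(0.8, -0.8))
    ca <- rbind(s1$ca, turn, s2$ca)
    cb <- rbind(s1$cb, turn + matrix(c(0, 0, 1.4), 2, 3, byrow = TRUE), s2$cb)
    atoms <- lapply(seq_len(L), function(i) rbind(ca[i, ], cb[i, ]))
  } else {
    n1 <- ceiling(0.45 * (L - 4))
    n2 <- L - 4 - n1
    h1 <- helix_coords(n1)
    z1 <- (n1 - 1) * 1.5
    h2 <- helix_coords(n2, origin = c(9.5, 0, z1 + 1.0), flip = TRUE)
    loop_t <- seq(0.2, 0.8, length.out = 4)
    p0 <- h1$ca[n1, ]; p1 <- h2$ca[1, ]
    loop <- t(vapply(loop_t, function(t_) {
      p0 + t_ * (p1 - p0) + c(0, 3.5 * sin(pi * t_), 1.5 * sin(pi * t_))
    }, numeric(3)))
    ca <- rbind(h1$ca, loop, h2$ca)
    atoms <- c(
      lapply(seq_len(n1), function(i) rbind(h1$ca[i, ], h1$cb[i, ], h1$cg[i, ])),
      lapply(seq_len(4), function(i) rbind(loop[i, , drop = TRUE])),
      lapply(seq_len(n2), function(i) rbind(h2$ca[i, ], h2$cb[i, ], h2$cg[i, ]))
    )
  }
  protein_structure(id = id, sequence = sequence %||% strrep("A", L),
                    calpha = ca, atoms = atoms)
}

#' Family specification for the synthetic generator
#'
#' @param n number of proteins (>= 2).
#' @param L scaffold length.
#' @param sub_rate substitutions per site per unit time.
#' @param indel_rate expected indel events per unit time over the whole
#'   protein.
#' @param indel_mean mean indel length (geometric).
#' @param sigma structural drift scale: per-branch coordinate noise has
#'   standard deviation `sigma * sqrt(branch length)` angstrom.
#' @param tree newick string, `"star"` (all leaves at `height` from the
#'   root), or `NULL` for a balanced ultrametric tree of total height
#'   `height`.
#' @param height tree height used when `tree` is NULL or "star".
#' @param motif scaffold motif.
#' @param seed integer seed; the same seed reproduces the family exactly.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n = 6, L = 60, sub_rate = 0.25, indel_rate = 1,
                        indel_mean = 2, sigma = 0.5, tree = NULL,
                        height = 0.75, motif = "mixed", seed = 1) {
  stopifnot(n >= 2, sub_rate >= 0, indel_rate >= 0, sigma >= 0)
  structure(list(n = n, L = L, sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, sigma = sigma, tree = tree,
                 height = height, motif = motif, seed = as.integer(seed)),
            class = "family_spec")
}

balanced_newick <- function(labels, height) {
  build <- function(lab, h) {
    if (length(lab) == 1) return(sprintf("%s:%g", lab, h))
    k <- ceiling(length(lab) / 2)
    sprintf("(%s,%s):%g", build(lab[1:k], h / 2),
            build(lab[(k + 1):length(lab)], h / 2), h / 2)
  }
  lab <- labels
  if (length(lab) == 1) return(sprintf("(%s:%g);", lab, height))
  k <- ceiling(length(lab) / 2)
  sprintf("(%s,%s);", build(lab[1:k], height), build(lab[(k + 1):length(lab)],
                                                     height))
}

#' Evolve a synthetic structure family along a planted tree
#'
#' Starting from a scaffold with a random sequence, evolves each branch with
#' Brownian coordinate drift (per-residue Gaussian noise of sd sigma *
#' sqrt(branch length), accumulating along the tree so structural similarity
#' decays with divergence time), Poisson substitutions (uniform exchange
#' among the other 19 amino acids) and geometric-length indels (never within
#' 3 positions of either terminus), applied consistently to sequence,
#' coordinates and the global truth alignment; each leaf finally receives a
#' random rigid transform. Fully deterministic for a fixed seed.
#'
#' @param spec a [family_spec()].
#' @return list of class `synthetic_family`: `structures` (leaf
#'   [protein_structure()]s), `truth_msa` (planted [msa()]), `times`
#'   (data.frame id1, id2, time: planted pairwise divergence times), `tree`
#'   (the planted `ape::phylo`), `spec`.
#' @export
evolve_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  labels <- sprintf("P%02d", seq_len(spec$n))
  nwk <- if (is.null(spec$tree)) {
    balanced_newick(labels, spec$height)
  } else if (identical(spec$tree, "star")) {
    sprintf("(%s);", paste(sprintf("%s:%g", labels, spec$height),
                           collapse = ","))
  } else spec$tree
  tree <- ape::read.tree(text = nwk)
  labels <- tree$tip.label
  root_seq <- sample(AA20, spec$L, replace = TRUE)
  scaffold <- make_scaffold(spec$L, spec$motif, id = "root",
                            sequence = paste(root_seq, collapse = ""))
  # site registry: global truth-MSA column ids in order
  registry <- seq_len(spec$L)
  next_id <- spec$L + 1L
  root_state <- list(seq = root_seq, sites = seq_len(spec$L),
                     ca = scaffold$calpha, atoms = scaffold$atoms)
  pick1 <- function(v) if (length(v) == 1) v else sample(v, 1)

  evolve_branch <- function(state, t_) {
    L <- length(state$seq)
    # structural drift: Brownian coordinate noise accumulating along the
    # branch (sd sigma * sqrt(t)); side-chain atoms move rigidly with the CA
    if (spec$sigma > 0 && t_ > 0) {
      off <- matrix(stats::rnorm(3 * L, 0, spec$sigma * sqrt(t_)), L, 3)
      state$ca <- state$ca + off
      state$atoms <- lapply(seq_len(L), function(i) {
        sweep(state$atoms[[i]], 2, off[i, ], `+`)
      })
    }
    # substitutions: Poisson number of events per site
    nev <- stats::rpois(L, spec$sub_rate * t_)
    for (i in which(nev > 0)) {
      for (e in seq_len(nev[i])) {
        state$seq[i] <- sample(setdiff(AA20, state$seq[i]), 1)
      }
    }
    # indels
    n_indel <- stats::rpois(1, spec$indel_rate * t_)
    for (e in seq_len(n_indel)) {
      L <- length(state$seq)
      if (L < 8) break
      len <- min(stats::rgeom(1, 1 / spec$indel_mean) + 1, 4)
      if (stats::runif(1) < 0.5) { # deletion
        maxstart <- L - 3 - len + 1
        if (maxstart < 4) next
        pos <- pick1(4:maxstart)
        idx <- pos:(pos + len - 1)
        state$seq <- state$seq[-idx]
        state$sites <- state$sites[-idx]
        state$ca <- state$ca[-idx, , drop = FALSE]
        state$atoms <- state$atoms[-idx]
      } else { # insertion after position pos
        pos <- pick1(3:(L - 3))
        new_ids <- next_id:(next_id + len - 1)
        next_id <<- next_id + len
        anchor <- match(state$sites[pos], registry)
        registry <<- append(registry, new_ids, after = anchor)
        p0 <- state$ca[pos, ]
        p1 <- state$ca[min(pos + 1, L), ]
        tpts <- seq_len(len) / (len + 1)
        nca <- t(vapply(tpts, function(t2) {
          p0 + t2 * (p1 - p0) + c(1.2 * sin(pi * t2), 1.2 * cos(pi * t2),
                                  0.8 * sin(pi * t2))
        }, numeric(3)))
        natoms <- lapply(seq_len(len), function(k) nca[k, , drop = FALSE])
        state$seq <- append(state$seq, sample(AA20, len, replace = TRUE),
                            after = pos)
        state$sites <- append(state$sites, new_ids, after = pos)
        state$ca <- rbind(state$ca[seq_len(pos), , drop = FALSE], nca,
                          state$ca[(pos + 1):L, , drop = FALSE])
        state$atoms <- append(state$atoms, natoms, after = pos)
      }
    }
    state
  }

  leaf_states <- vector("list", spec$n)
  names(leaf_states) <- labels
  recurse <- function(node, state) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0) return()
    for (k in seq_along(kids)) {
      child <- kids[k]
      blen <- tree$edge.length[which(tree$edge[, 1] == node &
                                       tree$edge[, 2] == child)]
      st <- evolve_branch(state, blen)
      if (child <= length(labels)) {
        leaf_states[[tree$tip.label[child]]] <<- st
      } else {
        recurse(child, st)
      }
    }
  }
  root_node <- length(labels) + 1L
  recurse(root_node, root_state)

  structures <- vector("list", spec$n)
  for (k in seq_len(spec$n)) {
    st <- leaf_states[[labels[k]]]
    rot <- random_rotation()
    trans <- stats::runif(3, -20, 20)
    structures[[k]] <- protein_structure(
      id = labels[k], sequence = paste(st$seq, collapse = ""),
      calpha = apply_transform(st$ca, rot, trans),
      atoms = lapply(st$atoms, function(a) apply_transform(a, rot, trans))
    )
  }
  # truth MSA from site registry
  rows <- vapply(seq_len(spec$n), function(k) {
    st <- leaf_states[[labels[k]]]
    chars <- rep("-", length(registry))
    chars[match(st$sites, registry)] <- st$seq
    paste(chars, collapse = "")
  }, "")
  truth <- msa(labels, rows)
  dmat <- ape::cophenetic.phylo(tree)[labels, labels]
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  times <- data.frame(id1 = labels[pairs[, 1]], id2 = labels[pairs[, 2]],
                      time = dmat[pairs], stringsAsFactors = FALSE)
  structure(list(structures = structures, truth_msa = truth, times = times,
                 tree = tree, spec = spec),
            class = "synthetic_family")
}

#' Write a synthetic family as PDB files plus manifest and truth MSA
#'
#' Materializes a family on disk so the command-line driver can be exercised
#' end to end: one single-chain PDB per structure, a manifest listing them,
#' and the planted truth alignment in FASTA.
#'
#' @param family a `synthetic_family` from [evolve_family()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- character(0)
  for (s in family$structures) {
    p <- file.path(dir, paste0(s$id, ".pdb"))
    write_structure_pdb(s, p)
    lines <- c(lines, paste(p, s$chain, s$id))
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c("# synthetic family manifest", lines), manifest)
  write_msa(family$truth_msa, file.path(dir, "truth.fasta"))
  invisible(manifest)
}

aa1to3 <- function(a) {
  m <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", X = "UNK")
  out <- m[a]
  out[is.na(out)] <- "UNK"
  unname(out)
}

pdb_atom_lines <- function(s, xyz_list = NULL, serial0 = 0L) {
  seq1 <- strsplit(s$sequence, "")[[1]]
  elety <- c("CA", "CB", "CG", "CD", "CE")
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(s$L)) {
    xyz <- if (is.null(xyz_list)) s$atoms[[i]] else xyz_list[[i]]
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial %% 100000, elety[min(a, 5)], aa1to3(seq1[i]), s$chain,
        s$resno[i], xyz[a, 1], xyz[a, 2], xyz[a, 3],
        substr(elety[min(a, 5)], 1, 1)))
    }
  }
  lines
}

#' Write one structure as a minimal PDB file
#' @param s a [protein_structure()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure_pdb <- function(s, path) {
  writeLines(c(pdb_atom_lines(s), "END"), path)
  invisible(path)
}
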