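# Structure input, contact maps, secondary structure, grouping, MSA I/O.

test_that("PDB round-trip reads back a tiny synthetic chain", {
  s <- toy_structure("t_A", matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0),
                                   3, 3, byrow = TRUE))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, p)
  r <- read_structure(p, chain = "A", name = "t")
  expect_equal(r$L, 3)
  expect_equal(r$sequence, "AAA")
  expect_equal(r$calpha, s$calpha, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("residues lacking a C-alpha are dropped with a warning", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   4      11.400   0.000   0.000  1.00  0.00           C",
    "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p)
  expect_warning(r <- read_structure(p, "A"), "without C-alpha")
  expect_equal(r$L, 3)
})

test_that("a missing chain is an error", {
  s <- make_scaffold(10, "helix")
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, p)
  expect_error(read_structure(p, chain = "Z"), "chain not found")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("contact definition follows the 4.5 A heavy-atom cutoff and min_sep", {
  ca <- matrix(0, 8, 3)
  ca[, 1] <- seq(0, by = 3.8, length.out = 8)
  atoms <- lapply(seq_len(8), function(i) ca[i, , drop = FALSE])
  # place extra heavy atoms of residues 1 and 6 at controlled distance
  near <- function(gap) {
    a <- atoms
    a[[1]] <- rbind(a[[1]], c(0, 5, 0))
    a[[6]] <- rbind(a[[6]], c(0, 5 + gap, 0))
    a
  }
  s_in <- toy_structure("in", ca, atoms = near(4.4))
  s_out <- toy_structure("out", ca, atoms = near(4.6))
  expect_equal(s_in$contacts[1, 6], 1L)
  expect_equal(s_out$contacts[1, 6], 0L)
  # min_sep excludes near-diagonal pairs regardless of distance
  s_close <- toy_structure("cl", matrix(stats::rnorm(24, sd = 1), 8, 3))
  expect_true(all(s_close$contacts[abs(row(s_close$contacts) -
                                         col(s_close$contacts)) < 3] == 0))
})

test_that("contact matrix equals the brute-force all-atom-pairs scan", {
  set.seed(31)
  ca <- matrix(stats::rnorm(30, sd = 4), 10, 3)
  atoms <- lapply(seq_len(10), function(i) {
    rbind(ca[i, ], ca[i, ] + stats::rnorm(3, sd = 1.5))
  })
  s <- toy_structure("bf", ca, atoms = atoms)
  expect_identical(s$contacts, brute_contacts(atoms))
})

test_that("contact matrices are invariant under rigid transforms", {
  set.seed(32)
  s <- make_scaffold(30, "mixed", id = "m")
  tr <- random_rigid()
  s2 <- transform_structure(s, tr$rotation, tr$translation)
  s2$contacts <- compute_contacts(s2)
  expect_identical(s$contacts, s2$contacts)
})

test_that("secondary structure assignment matches the built-in geometry criteria", {
  helix <- make_scaffold(12, "helix")
  expect_gte(sum(strsplit(helix$sstruct, "")[[1]] == "H"), 8)
  strand <- toy_structure("e", strand_coords_test(12))
  ssv <- strsplit(assign_secondary_structure(strand$calpha), "")[[1]]
  expect_equal(sum(ssv == "H"), 0)
  expect_gte(mean(ssv %in% c("E", "C")), 0.5)
  set.seed(5)
  coil <- matrix(stats::runif(60, 0, 18), 20, 3)
  sc <- strsplit(assign_secondary_structure(coil), "")[[1]]
  expect_lte(mean(sc == "H"), 0.2)
  expect_equal(assign_secondary_structure(matrix(0, 4, 3)), "CCCC")
})

test_that("DSSP override parses and maps to H/E/C", {
  hdr <- "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  row <- function(i, ch, aa, ss) {
    sprintf("%5d%5d %s %s  %s", i, i, ch, aa, ss)
  }
  p <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("== header ==", hdr,
               row(1, "A", "A", "H"), row(2, "A", "L", "G"),
               row(3, "A", "V", "E"), row(4, "A", "G", "B"),
               row(5, "A", "K", "T"), row(6, "B", "A", "H")), p)
  expect_equal(read_dssp(p, "A"), "HHEEC")
})

test_that("sequence grouping is single linkage over the one-mutation relation", {
  mk <- function(id, seq) {
    toy_structure(id, matrix(seq_len(3 * nchar(seq)), ncol = 3) * 2.0,
                  sequence = seq)
  }
  g1 <- group_sequences(list(mk("a", "AAAA"), mk("b", "AAAA"), mk("c", "AAAC")))
  expect_length(g1, 1)
  expect_setequal(g1[[1]]$member_ids, c("a", "b", "c"))
  g2 <- group_sequences(list(mk("a", "AAAA"), mk("b", "CCCC")))
  expect_length(g2, 2)
  # transitive closure: AACC links to AAAA only through AAAC
  g3 <- group_sequences(list(mk("a", "AAAA"), mk("b", "AAAC"), mk("c", "AACC")))
  expect_length(g3, 1)
  # oracle: explicit transitive closure over the pair relation
  seqs <- c("AAAA", "AAAC", "AACC", "GGGG", "GGGA")
  structs <- lapply(seq_along(seqs), function(i) mk(letters[i], seqs[i]))
  grp <- group_sequences(structs)
  rel <- outer(seqs, seqs, Vectorize(function(x, y) {
    nchar(x) == nchar(y) && sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) <= 1
  }))
  reach <- rel
  for (k in seq_along(seqs)) reach <- reach | (reach %*% reach > 0)
  n_components <- length(unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
  expect_length(grp, n_components)
  # grouping partitions the input
  expect_setequal(unlist(lapply(grp, `[[`, "member_ids")), letters[1:5])
})

test_that("MSA FASTA round-trips are lossless including 60-column wrapping", {
  x <- msa(c("s1", "s2"), c("ACD-EF", "AC-DEF"))
  p <- withr::local_tempfile(fileext = ".fasta")
  write_msa(x, p)
  expect_equal(read_msa(p)$rows, x$rows)
  long <- msa(c("a", "b"),
              c(strrep("ACDEFGHIKL", 13), strrep("ACDEFGHIK-", 13)))
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(long, p2, width = 60)
  r2 <- read_msa(p2)
  expect_equal(r2$rows, long$rows)
  expect_equal(r2$names, long$names)
})

test_that("malformed MSAs are rejected", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "ACD"), p)
  expect_error(read_msa(p), "unequal row lengths")
  expect_error(msa(c("a", "a"), c("AC", "AC")), "duplicate")
})

test_that("manifest parsing skips comments and fills defaults", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "x.pdb A prot1", "y.pdb B", ""), p)
  m <- read_manifest(p)
  expect_equal(m$name, c("prot1", "y"))
  expect_equal(m$chain, c("A", "B"))
})

test_that("NCBI matrix text parses back to the built-in BLOSUM62", {
  b <- read_substitution_matrix()
  aa <- rownames(b)[1:23]
  p <- withr::local_tempfile(fileext = ".txt")
  lines <- c("# test matrix", paste(aa, collapse = " "),
             vapply(aa, function(r) {
               paste(r, paste(b[r, aa], collapse = " "))
             }, ""))
  writeLines(lines, p)
  m <- read_substitution_matrix(p)
  expect_equal(m[aa, aa], b[aa, aa], ignore_attr = TRUE)
  bh <- rescale_submat(b)
  expect_true(all(bh >= 0 & bh <= 1))
  expect_equal(max(bh), 1)
})
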