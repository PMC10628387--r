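# End-to-end driver: read structures, build or read starting pairwise
# alignments, refine them, seed an MSA from cliques, refine progressively,
# and emit the output-file suite.

#' Run configuration for the aligner
#'
#' @param manifest path to the structure manifest (see [read_manifest()]).
#' @param mode `"seq"` (de novo pairwise alignments) or `"ali"` (start from
#'   an input MSA).
#' @param msa_path aligned FASTA path (required for mode "ali"); its names
#'   must match the manifest names.
#' @param out_prefix prefix of all output files.
#' @param submat_path optional NCBI-format substitution matrix.
#' @param max_iter refinement iteration cap (default 5).
#' @param max_steps progressive iteration cap (default 7).
#' @param gap_open,gap_ext affine gap parameters for de novo / profile DP.
#' @param verbosity 0 (quiet), 1 (progress), 2 (debug) to stderr.
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest, mode = c("seq", "ali"), msa_path = NULL,
                       out_prefix = "pcali_out", submat_path = NULL,
                       max_iter = 5, max_steps = 7,
                       gap_open = 0.35, gap_ext = 0.05, verbosity = 1) {
  mode <- match.arg(mode)
  if (mode == "ali" && is.null(msa_path)) {
    stop("mode 'ali' requires an input MSA path")
  }
  stopifnot(max_iter >= 1, max_steps >= 1)
  structure(list(manifest = manifest, mode = mode, msa_path = msa_path,
                 out_prefix = out_prefix, submat_path = submat_path,
                 max_iter = max_iter, max_steps = max_steps,
                 gap_open = gap_open, gap_ext = gap_ext,
                 verbosity = verbosity),
            class = "run_config")
}

vlog <- function(cfg, level, ...) {
  if (cfg$verbosity >= level) message(...)
}

stage_avg <- function(stage, score_list) {
  df <- do.call(rbind, lapply(score_list, function(sc) {
    data.frame(ali = sc$ali, SI = sc$SI, SS = sc$ss_id, TM = sc$TM,
               CO = ifelse(is.na(sc$CO), NA, sc$CO), PC = sc$PC)
  }))
  data.frame(stage = stage, kind = "pairwise", ali = mean(df$ali),
             SI = mean(df$SI), SS = mean(df$SS), TM = mean(df$TM),
             CO = mean(df$CO, na.rm = TRUE), PC = mean(df$PC),
             stringsAsFactors = FALSE)
}

pair_div_table <- function(scores) {
  data.frame(id1 = scores$id1, id2 = scores$id2,
             TN = tn_divergence(scores$SI),
             TMdiv = tm_divergence(scores$TM),
             CD = contact_divergence(scores$CO, pmax(scores$L_ali, 1)),
             PCdiv = pc_divergence(scores$PC, pmax(scores$L_ali, 1)),
             stringsAsFactors = FALSE)
}

nj_newick <- function(div, ids) {
  if (length(ids) == 2) {
    d <- div[ids[1], ids[2]]
    return(sprintf("(%s:%g,%s:%g);", ids[1], d / 2, ids[2], d / 2))
  }
  tr <- ape::nj(stats::as.dist(div[ids, ids]))
  ape::write.tree(tr)
}

#' Run the full alignment pipeline
#'
#' Either from a parsed configuration (paths) or from in-memory structures.
#' Steps: group near-identical sequences and pick representatives; obtain
#' starting pairwise alignments (de novo or projected from the input MSA);
#' apply the SS/TM/CO/PC refinements to every representative pair; seed an
#' MSA from the maximal cliques of the PC-refined alignment graph; refine it
#' with the progressive aligner; select the MSA with the largest average
#' PC_sim.
#'
#' @param structures list of [protein_structure()] objects.
#' @param mode "seq" or "ali".
#' @param input_msa an [msa()] (mode "ali").
#' @param submat substitution matrix (default BLOSUM62).
#' @param max_iter,max_steps,gap_open,gap_ext see [run_config()].
#' @param verbosity message level.
#' @return list of class `pcali_result`: `final_msa`, `progressive`
#'   (the [run_progressive()] result), `seed_msa`, `groups`,
#'   `representatives` (structure list), `stage_table` (per-stage average
#'   scores), `pair_scores` (final-MSA pair table), `pair_div`, `pa_stages`
#'   (per-pair refined alignments by stage), `structures`.
#' @export
run_pipeline <- function(structures, mode = c("seq", "ali"), input_msa = NULL,
                         submat = NULL, max_iter = 5, max_steps = 7,
                         gap_open = 0.35, gap_ext = 0.05, verbosity = 0) {
  mode <- match.arg(mode)
  cfg <- list(verbosity = verbosity)
  groups <- group_sequences(structures)
  reps <- lapply(groups, function(g) structures[[g$representative_index]])
  ids <- vapply(reps, `[[`, "", "id")
  n <- length(reps)
  if (n < 2) stop("need at least two sequence groups")
  vlog(cfg, 1, "representatives: ", n, " of ", length(structures),
       " structures")
  if (mode == "ali") {
    stopifnot(!is.null(input_msa))
    miss <- setdiff(ids, input_msa$names)
    if (length(miss)) stop("input MSA lacks sequences: ",
                           paste(miss, collapse = ", "))
  }
  # starting pairwise alignments
  pairs_idx <- utils::combn(n, 2)
  pa0 <- list()
  for (k in seq_len(ncol(pairs_idx))) {
    a <- pairs_idx[1, k]; b <- pairs_idx[2, k]
    pa0[[k]] <- if (mode == "seq") {
      denovo_pa(reps[[a]], reps[[b]], submat, gap_open, gap_ext)
    } else {
      pa_from_msa(input_msa, ids[a], ids[b])
    }
  }
  vlog(cfg, 1, "starting pairwise alignments done (", length(pa0), " pairs)")
  # refinements per pair
  stages <- c("input", "SS_ali", "TM_ali", "CO_ali", "PC_ali")
  pa_stages <- list()
  score_stage <- stats::setNames(vector("list", length(stages)), stages)
  pc_pas <- list()
  for (k in seq_len(ncol(pairs_idx))) {
    a <- pairs_idx[1, k]; b <- pairs_idx[2, k]
    s1 <- reps[[a]]; s2 <- reps[[b]]
    res <- list(input = NULL)
    sc_in <- score_pa(pa0[[k]], s1, s2)
    score_stage$input <- c(score_stage$input, list(sc_in))
    ssr <- ss_realign(pa0[[k]], s1, s2)
    score_stage$SS_ali <- c(score_stage$SS_ali, list(ssr$scores_out))
    for (tg in c("TM", "CO", "PC")) {
      rr <- refine_pa(pa0[[k]], s1, s2, tg, max_iter)
      score_stage[[paste0(tg, "_ali")]] <-
        c(score_stage[[paste0(tg, "_ali")]], list(rr$scores_out))
      res[[tg]] <- rr$refined
    }
    pa_stages[[k]] <- list(id1 = ids[a], id2 = ids[b], input = pa0[[k]],
                           SS = ssr$refined, TM = res$TM, CO = res$CO,
                           PC = res$PC)
    pc_pas[[k]] <- res$PC
  }
  vlog(cfg, 1, "pairwise refinements done")
  seed <- clique_msa(pc_pas, reps)
  vlog(cfg, 1, "clique MSA: ", msa_width(seed), " columns")
  prog <- run_progressive(reps, seed, max_steps, gap_open = gap_open,
                          gap_ext = gap_ext)
  vlog(cfg, 1, "progressive refinement done; avg PC_sim = ",
       sprintf("%.4f", prog$avg_pc))
  # stage table
  st <- rbind(
    do.call(rbind, lapply(stages, function(s) stage_avg(s, score_stage[[s]]))),
    do.call(rbind, lapply(seq_len(nrow(prog$log)), function(r) {
      x <- prog$msas[[r]]
      scl <- msa_pair_scores(x, reps)
      data.frame(stage = if (r == 1) "clique_msa" else
        paste0("progressive_", r - 1), kind = "msa",
        ali = mean(scl$ali), SI = mean(scl$SI), SS = mean(scl$SS),
        TM = mean(scl$TM), CO = mean(scl$CO, na.rm = TRUE),
        PC = mean(scl$PC), stringsAsFactors = FALSE)
    }))
  )
  sel <- msa_pair_scores(prog$msa, reps)
  st <- rbind(st, data.frame(stage = "selected", kind = "msa",
                             ali = mean(sel$ali),
                             SI = mean(sel$SI), SS = mean(sel$SS),
                             TM = mean(sel$TM),
                             CO = mean(sel$CO, na.rm = TRUE),
                             PC = mean(sel$PC), stringsAsFactors = FALSE))
  structure(list(final_msa = prog$msa, progressive = prog, seed_msa = seed,
                 groups = groups, representatives = reps,
                 stage_table = st, pair_scores = sel,
                 pair_div = pair_div_table(sel), pa_stages = pa_stages,
                 structures = structures),
            class = "pcali_result")
}

# Scores of every structure pair under the final MSA, mapping each structure
# to its group representative's row (between-group structure similarity uses
# the maximum across member conformations at the representative level).
all_structure_scores <- function(result) {
  structures <- result$structures
  groups <- result$groups
  rep_of <- integer(length(structures))
  for (gi in seq_along(groups)) rep_of[groups[[gi]]$member_index] <- gi
  ids <- vapply(structures, `[[`, "", "id")
  rep_ids <- vapply(result$representatives, `[[`, "", "id")
  out <- list()
  n <- length(structures)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ga <- rep_of[a]; gb <- rep_of[b]
    if (ga == gb) {
      pa <- identity_pa(ids[a], ids[b], min(structures[[a]]$L,
                                            structures[[b]]$L))
      sc <- score_pa(pa, structures[[a]], structures[[b]])
    } else {
      pa <- pa_from_msa(result$final_msa, rep_ids[ga], rep_ids[gb])
      sc <- score_pa(pa, structures[[a]], structures[[b]])
    }
    out[[length(out) + 1]] <- data.frame(
      id1 = ids[a], id2 = ids[b], ali = sc$ali, SI = sc$SI, SS = sc$ss_id,
      TM = sc$TM, CO = ifelse(is.na(sc$CO), NA, sc$CO), PC = sc$PC,
      L_ali = sc$L_ali, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write the output-file suite of a pipeline run
#'
#' Emits `<prefix>.sim`, `<prefix>.div` (all structure pairs),
#' `<prefix>.prot.sim`, `<prefix>.prot.div` (representative pairs),
#' `<prefix>.PCAli.fas` (final MSA), `<prefix>.PCAli_ss.msa` (secondary
#' structure MSA), `<prefix>.PCAli.tree` (neighbor-joining tree from PC_div),
#' `<prefix>.PCAli.pdb` (one MODEL per structure with superposed
#' coordinates), `<prefix>_summary.dat` (per-stage average scores) and a
#' stub `<prefix>.id`.
#'
#' @param result a `pcali_result` from [run_pipeline()].
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, prefix) {
  paths <- character(0)
  emit <- function(p) { paths <<- c(paths, p); p }
  allsc <- all_structure_scores(result)
  write_sim_table(allsc, emit(paste0(prefix, ".sim")))
  write_div_table(pair_div_table(allsc), emit(paste0(prefix, ".div")))
  write_sim_table(result$pair_scores, emit(paste0(prefix, ".prot.sim")))
  write_div_table(result$pair_div, emit(paste0(prefix, ".prot.div")))
  write_msa(result$final_msa, emit(paste0(prefix, ".PCAli.fas")))
  # secondary-structure MSA
  reps <- result$representatives
  ss_rows <- vapply(seq_along(reps), function(k) {
    row <- strsplit(result$final_msa$rows[k], "")[[1]]
    ss <- strsplit(reps[[k]]$sstruct, "")[[1]]
    idx <- cumsum(row != "-")
    out <- ifelse(row == "-", "-", ss[pmax(idx, 1)])
    paste(out, collapse = "")
  }, "")
  write_msa(msa(result$final_msa$names, ss_rows, drop_allgap = FALSE),
            emit(paste0(prefix, ".PCAli_ss.msa")))
  # NJ tree on PC_div
  dm <- divergence_matrix(result$pair_div, "PCdiv",
                          ids = result$final_msa$names)
  writeLines(nj_newick(dm$matrix, result$final_msa$names),
             emit(paste0(prefix, ".PCAli.tree")))
  # superposed PDB: one MODEL per representative
  tr <- result$progressive$superposition$transforms
  lines <- character(0)
  for (k in seq_along(reps)) {
    s <- reps[[k]]
    xyz <- lapply(s$atoms, function(a) {
      apply_transform(a, tr[[k]]$rotation, tr[[k]]$translation)
    })
    lines <- c(lines, sprintf("MODEL     %4d", k),
               pdb_atom_lines(s, xyz), "ENDMDL")
  }
  writeLines(c(lines, "END"), emit(paste0(prefix, ".PCAli.pdb")))
  st <- result$stage_table
  num <- vapply(st, is.numeric, TRUE)
  st[num] <- lapply(st[num], function(x) sprintf("%.4f", x))
  utils::write.table(st, emit(paste0(prefix, "_summary.dat")),
                     quote = FALSE, row.names = FALSE)
  writeLines("# conservation-pattern analysis: not produced by this tool version",
             emit(paste0(prefix, ".id")))
  invisible(paths)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()] and [write_outputs()]. Flags:
#' `-i <manifest>`, `-seq` or `-ali <msa.fasta>`, `-o <prefix>`,
#' `-mat <substitution matrix>`, `-max_iter <k>`, `-max_steps <k>`,
#' `-q` (quiet), `-v` (debug).
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return integer exit code: 0 success, 2 configuration error, 1 runtime
#'   failure (partial outputs are removed).
#' @export
pc_ali_main <- function(argv) {
  usage <- paste("usage: pc_ali -i <manifest> [-seq | -ali <msa.fasta>]",
                 "[-o <prefix>] [-mat <file>] [-max_iter k] [-max_steps k]",
                 "[-q | -v]")
  opts <- list(manifest = NULL, mode = "seq", msa_path = NULL,
               out_prefix = "pcali_out", submat_path = NULL,
               max_iter = 5, max_steps = 7, verbosity = 1)
  i <- 1
  need <- function(i) {
    if (i + 1 > length(argv)) stop("missing value for ", argv[i], call. = FALSE)
    argv[i + 1]
  }
  cfg <- tryCatch({
    while (i <= length(argv)) {
      a <- argv[i]
      if (a %in% c("-i", "--input")) { opts$manifest <- need(i); i <- i + 2 }
      else if (a == "-seq") { opts$mode <- "seq"; i <- i + 1 }
      else if (a %in% c("-ali", "--ali")) {
        opts$mode <- "ali"; opts$msa_path <- need(i); i <- i + 2
      }
      else if (a %in% c("-o", "--out")) { opts$out_prefix <- need(i); i <- i + 2 }
      else if (a %in% c("-mat", "--matrix")) {
        opts$submat_path <- need(i); i <- i + 2
      }
      else if (a == "-max_iter") { opts$max_iter <- as.integer(need(i)); i <- i + 2 }
      else if (a == "-max_steps") { opts$max_steps <- as.integer(need(i)); i <- i + 2 }
      else if (a == "-q") { opts$verbosity <- 0; i <- i + 1 }
      else if (a == "-v") { opts$verbosity <- 2; i <- i + 1 }
      else stop("unknown argument: ", a, call. = FALSE)
    }
    if (is.null(opts$manifest)) stop("-i <manifest> is required", call. = FALSE)
    run_config(opts$manifest, opts$mode, opts$msa_path,
               opts$out_prefix, opts$submat_path, opts$max_iter,
               opts$max_steps, verbosity = opts$verbosity)
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e))
    message(usage)
    NULL
  })
  if (is.null(cfg)) return(2L)
  suffixes <- c(".sim", ".div", ".prot.sim", ".prot.div", ".PCAli.fas",
                ".PCAli_ss.msa", ".PCAli.tree", ".PCAli.pdb",
                "_summary.dat", ".id")
  code <- tryCatch({
    man <- read_manifest(cfg$manifest)
    structures <- lapply(seq_len(nrow(man)), function(k) {
      s <- read_structure(man$path[k], man$chain[k], man$name[k])
      s$id <- man$name[k]
      s
    })
    input_msa <- if (cfg$mode == "ali") read_msa(cfg$msa_path) else NULL
    submat <- if (!is.null(cfg$submat_path)) {
      read_substitution_matrix(cfg$submat_path)
    } else NULL
    result <- run_pipeline(structures, cfg$mode, input_msa, submat,
                           cfg$max_iter, cfg$max_steps, cfg$gap_open,
                           cfg$gap_ext, cfg$verbosity)
    write_outputs(result, cfg$out_prefix)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    partial <- paste0(cfg$out_prefix, suffixes)
    suppressWarnings(file.remove(partial[file.exists(partial)]))
    1L
  })
  code
}
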