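# Evolutionary divergences inferred from similarity measures: Tajima-Nei-form
# transforms -ln((S - S0)/(1 - S0)) with measure-specific no-homology
# baselines. Divergences are only defined for similarities above baseline;
# below it they are UNDEFINED, represented as NA.

#' Divergence baselines
#'
#' Similarity values expected without homology: SI0 = 0.05, TM0 = 0.167,
#' ali0 = 0.5, and the length-dependent contact-overlap baseline of
#' [q_contact()].
#'
#' @return list with SI0, TM0, ali0 and the q(L) coefficients.
#' @export
divergence_params <- function() {
  list(SI0 = 0.05, TM0 = 0.167, ali0 = 0.5,
       q_coef = c(0.39, -0.55, 6.64, -0.67))
}

#' Contact overlap expected under convergent evolution
#'
#' q(L) = 0.39 L^-0.55 + 6.64 L^-0.67, decreasing in the number of aligned
#' residues L.
#'
#' @param L number of aligned residues (>= 1).
#' @return baseline CO in (0, 1) for usual L.
#' @export
q_contact <- function(L) {
  stopifnot(all(L >= 1))
  0.39 * L^-0.55 + 6.64 * L^-0.67
}

tn_form <- function(S, S0, denom = 1 - S0) {
  n <- max(length(S), length(S0))
  S <- rep_len(S, n)
  S0 <- rep_len(S0, n)
  denom <- rep_len(denom, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(S) & S > S0
  out[ok] <- -log((S[ok] - S0[ok]) / denom[ok])
  out
}

#' Tajima-Nei divergence from sequence identity
#'
#' TNdiv = -ln((SI - 0.05)/0.95): the maximum-likelihood divergence time
#' under a Jukes-Cantor-style model with uniform amino-acid exchange.
#' UNDEFINED (NA) when SI <= 0.05.
#'
#' @param SI sequence identity in [0, 1] (vectorized).
#' @return nonnegative divergence, or NA.
#' @export
tn_divergence <- function(SI) tn_form(SI, divergence_params()$SI0)

#' TM divergence from the TM-score
#'
#' TMdiv = -ln((TM - 0.167)/0.833); 0.167 is the TM-score expected under
#' convergent evolution. UNDEFINED (NA) when TM <= 0.167.
#'
#' @param TM TM-score in [0, 1] (vectorized).
#' @return nonnegative divergence, or NA.
#' @export
tm_divergence <- function(TM) tn_form(TM, divergence_params()$TM0)

#' Contact divergence from the contact overlap
#'
#' CD = -ln((CO - q(L))/(1 - q(L))) with q(L) from [q_contact()], L the
#' number of aligned residues of the pair. UNDEFINED (NA) when CO <= q(L).
#'
#' @param CO contact overlap in [0, 1] (vectorized).
#' @param L number of aligned residues (recycled).
#' @return nonnegative divergence, or NA.
#' @export
contact_divergence <- function(CO, L) {
  q <- q_contact(L)
  tn_form(CO, q)
}

#' Baseline PC similarity expected without homology
#'
#' PC0(L) = (0.84 ali0 + 0.79 SI0 + 0.95 TM0 + 0.95 q(L)) / 3.53 with
#' ali0 = 0.5.
#'
#' @param L number of aligned residues.
#' @return PC0 in (0, 1).
#' @export
pc0_baseline <- function(L) {
  p <- divergence_params()
  w <- pc_weights()
  (w$w_ali * p$ali0 + w$w_SI * p$SI0 + w$w_TM * p$TM0 +
     w$w_CO * q_contact(L)) / w$norm
}

#' PC divergence from the hybrid PC similarity
#'
#' PCdiv = -ln((PC - PC0)/(1 - PC0)) with PC0 from [pc0_baseline()]. The
#' denominator follows the same form as the other divergences; set
#' `denom_one_minus_pc = TRUE` for the alternative (1 - PC) denominator.
#' UNDEFINED (NA) when PC <= PC0.
#'
#' @param PC PC similarity in [0, 1] (vectorized).
#' @param L number of aligned residues (recycled).
#' @param denom_one_minus_pc use (1 - PC) instead of (1 - PC0).
#' @return nonnegative divergence, or NA.
#' @export
pc_divergence <- function(PC, L, denom_one_minus_pc = FALSE) {
  PC0 <- pc0_baseline(L)
  if (denom_one_minus_pc) tn_form(PC, PC0, denom = 1 - PC) else tn_form(PC, PC0)
}

#' Divergence matrix for tree building
#'
#' Builds the symmetric divergence matrix of one measure from a pairwise
#' score table. UNDEFINED (NA) entries are imputed as (max defined
#' divergence) + 1 so that pairs without homology signal stay most distant;
#' the original NA pattern is returned alongside for output files.
#'
#' @param scores data.frame with columns id1, id2 and the divergence column.
#' @param measure name of the divergence column (e.g. "PCdiv").
#' @param ids optional id ordering (default: order of appearance).
#' @return list with `matrix` (imputed, zero diagonal), `raw` (with NA), and
#'   `ids`.
#' @export
divergence_matrix <- function(scores, measure, ids = NULL) {
  if (is.null(ids)) ids <- unique(c(scores$id1, scores$id2))
  n <- length(ids)
  raw <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(raw) <- 0
  for (k in seq_len(nrow(scores))) {
    v <- scores[[measure]][k]
    raw[scores$id1[k], scores$id2[k]] <- v
    raw[scores$id2[k], scores$id1[k]] <- v
  }
  off <- raw[upper.tri(raw)]
  if (all(is.na(off))) stop("no homology signal: all divergences undefined")
  m <- raw
  m[is.na(m)] <- max(off, na.rm = TRUE) + 1
  list(matrix = m, raw = raw, ids = ids)
}

#' Write a pairwise divergence table
#'
#' Whitespace-separated columns `id1 id2 TN TMdiv CD PCdiv`; UNDEFINED
#' divergences are written as NA.
#'
#' @param div data.frame with columns id1, id2, TN, TMdiv, CD, PCdiv.
#' @param path output path (conventionally suffixed `.div`).
#' @return invisibly, `path`.
#' @export
write_div_table <- function(div, path) {
  df <- div[, c("id1", "id2", "TN", "TMdiv", "CD", "PCdiv")]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "NA",
                                                sprintf("%.4f", x)))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
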