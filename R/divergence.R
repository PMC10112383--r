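#' Delta-NES divergence between two conditions
#'
#' For gene-set terms scored in two conditions, computes the difference
#' in normalized enrichment score and classifies terms as oppositely
#' regulated when the delta exceeds a threshold (default 3). The delta
#' is absolute by default; `signed = TRUE` keeps `nes_a - nes_b`. A sign
#' switch (`nes_a * nes_b < 0`) is always recorded and can be made part
#' of the opposite-regulation call with `require_sign_switch`.
#'
#' @param records data.frame with term, nes_a, nes_b and, when
#'   filtering, fdr_a and fdr_b. Terms must be unique.
#' @param delta_threshold opposite-regulation cutoff on the delta.
#' @param require_both_significant keep only terms with both FDRs below
#'   `fdr_max` before classifying.
#' @param fdr_max per-condition FDR cutoff (default 0.1).
#' @param signed report `nes_a - nes_b` instead of its absolute value
#'   (classification always uses the absolute delta).
#' @param require_sign_switch stricter call: opposite also needs the NES
#'   signs to differ.
#' @return list with `records` (term, nes_a, nes_b, delta, sign_switch,
#'   oppositely_regulated) and `summary` (n_terms, n_opposite,
#'   percent_opposite rounded half-up to 1 decimal).
#' @export
delta_nes <- function(records, delta_threshold = 3,
                      require_both_significant = FALSE, fdr_max = 0.1,
                      signed = FALSE, require_sign_switch = FALSE) {
  assert_columns(records, c("term", "nes_a", "nes_b"), "NES table")
  if (anyDuplicated(records$term)) stopf("duplicate terms in the NES table")
  r <- records
  if (require_both_significant) {
    assert_columns(r, c("fdr_a", "fdr_b"), "NES table")
    r <- r[r$fdr_a < fdr_max & r$fdr_b < fdr_max, , drop = FALSE]
  }
  d <- r$nes_a - r$nes_b
  sw <- r$nes_a * r$nes_b < 0
  opp <- abs(d) > delta_threshold
  if (require_sign_switch) opp <- opp & sw
  out <- data.frame(term = r$term, nes_a = r$nes_a, nes_b = r$nes_b,
                    delta = if (signed) d else abs(d),
                    sign_switch = sw, oppositely_regulated = opp)
  rownames(out) <- NULL
  n <- nrow(out); k <- sum(out$oppositely_regulated)
  list(records = out,
       summary = data.frame(
         n_terms = n, n_opposite = k,
         percent_opposite = if (n == 0) 0 else round_half_up(100 * k / n, 1)))
}

#' Delta motif-enrichment tables against a reference condition
#'
#' Matches motifs by name and reports `score_condition - score_reference`
#' per motif, ranked by absolute delta. Motifs absent from the reference
#' are kept with `reference_missing = TRUE` and `NA` delta.
#'
#' @param reference data.frame with motif and score (e.g. `-log10 p` or
#'   target coverage percent) for the reference condition.
#' @param others named list of such data.frames, one per condition.
#' @return named list of data.frames: motif, score, score_ref, delta,
#'   reference_missing.
#' @export
delta_motif <- function(reference, others) {
  assert_columns(reference, c("motif", "score"), "reference motif table")
  if (anyDuplicated(reference$motif)) {
    stopf("duplicate motif names in the reference table")
  }
  if (is.null(names(others))) stopf("condition tables must be named")
  lapply(others, function(tab) {
    assert_columns(tab, c("motif", "score"), "condition motif table")
    if (anyDuplicated(tab$motif)) {
      stopf("duplicate motif names in a condition table")
    }
    ref <- reference$score[match(tab$motif, reference$motif)]
    out <- data.frame(motif = tab$motif, score = tab$score,
                      score_ref = ref, delta = tab$score - ref,
                      reference_missing = is.na(ref))
    out <- out[order(out$reference_missing, -abs(out$delta), out$motif), ]
    rownames(out) <- NULL
    out
  })
}
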