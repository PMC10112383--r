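#' Filter a differential-expression table by printed thresholds
#'
#' A record passes when `|log2fc| > absfc_min` (strict) and it is
#' significant, where significant means `logpv > logpv_min` or — when
#' `use_padj` — additionally `padj < padj_max`. `logpv` is derived as
#' `-log10(pvalue)` when not supplied. Records with no usable
#' significance field are dropped with a warning.
#'
#' @param records data.frame with gene_id (or mirna_id), log2fc, and at
#'   least one of pvalue/logpv; padj when `use_padj`.
#' @param logpv_min,absfc_min strict lower thresholds.
#' @param use_padj also accept records with `padj < padj_max`.
#' @param padj_max adjusted-p cutoff used when `use_padj`.
#' @return the passing subset (rows of `records`).
#' @export
filter_deg <- function(records, logpv_min = 1, absfc_min = 0.37,
                       use_padj = FALSE, padj_max = 0.1) {
  assert_columns(records, "log2fc", "differential table")
  if (is.null(records$logpv)) {
    if (is.null(records$pvalue)) {
      stopf("differential table needs a 'logpv' or 'pvalue' column")
    }
    records$logpv <- -log10(records$pvalue)
  }
  sig <- records$logpv > logpv_min
  if (use_padj) {
    assert_columns(records, "padj", "differential table")
    sig <- sig | (records$padj < padj_max)
  }
  usable <- !is.na(sig) & !is.na(records$log2fc)
  if (any(!usable)) {
    warning(sprintf("%d record(s) lacking significance or fold change excluded",
                    sum(!usable)), call. = FALSE)
  }
  keep <- usable & sig & abs(records$log2fc) > absfc_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of drawing at least `hits` category members when
#' `set_size` items are drawn without replacement from a universe of
#' `universe` items of which `category_size` are in the category:
#' `P(X >= hits)`. `strict_tail = TRUE` computes `P(X > hits)` instead
#' (the literal reading of an upper tail that excludes the observed
#' count).
#'
#' @param hits overlap count.
#' @param set_size,category_size,universe the remaining margins.
#' @param strict_tail use `P(X > hits)`.
#' @return one-row data.frame: overlap_k, set_a_size, set_b_size,
#'   universe_n, pvalue, logpv.
#' @export
hypergeom_enrichment <- function(hits, set_size, category_size, universe,
                                 strict_tail = FALSE) {
  if (hits > min(set_size, category_size)) {
    stopf("hits (%d) exceeds min(set_size, category_size)", hits)
  }
  if (set_size > universe || category_size > universe) {
    stopf("set sizes cannot exceed the universe")
  }
  if (hits < 0 || set_size < 0 || category_size < 0 || universe < 1) {
    stopf("counts must be non-negative and universe >= 1")
  }
  q <- if (strict_tail) hits else hits - 1
  p <- stats::phyper(q, category_size, universe - category_size, set_size,
                     lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  data.frame(overlap_k = hits, set_a_size = set_size,
             set_b_size = category_size, universe_n = universe,
             pvalue = p, logpv = -log10(p))
}

#' Percentage overlap as printed in report tables
#'
#' `100 * in_both / (in_both + in_first_only)`, rounded half-up.
#' `digits = 1` reproduces one-decimal table percentages; `digits = 0`
#' the whole-percent style used for fractions quoted in text.
#'
#' @param in_both count of items in both sets.
#' @param in_first_only count of items in the first set only.
#' @param digits decimal places (half-up).
#' @return percentage, or `NA` when both counts are zero.
#' @export
percent_overlap <- function(in_both, in_first_only, digits = 1) {
  if (in_both < 0 || in_first_only < 0) stopf("counts must be >= 0")
  tot <- in_both + in_first_only
  if (tot == 0) return(NA_real_)
  round_half_up(100 * in_both / tot, digits)
}

#' Top-K factor-frequency enrichment from a ranked dataset table
#'
#' Given datasets ranked by similarity to a query cistrome, compares each
#' factor's share of the top `k` with its share of the whole collection:
#' `fold_change = (count_topk / k) / (total_factor / total_datasets)`.
#' A factor is called co-enriched when `fold_change > fc_threshold`.
#' Factors absent from the top `k` get fold change 0.
#'
#' @param ranked_datasets data.frame with dataset_id (unique) and factor,
#'   ordered best-first.
#' @param k depth of the top list (default 200).
#' @param fc_threshold co-enrichment fold-change cutoff (default 1.2).
#' @return data.frame: factor, count_topk, total_factor, k,
#'   total_datasets, fold_change, coenriched; sorted by fold change.
#' @export
factor_frequency_enrichment <- function(ranked_datasets, k = 200,
                                        fc_threshold = 1.2) {
  assert_columns(ranked_datasets, c("dataset_id", "factor"), "ranked table")
  if (anyDuplicated(ranked_datasets$dataset_id)) {
    stopf("dataset_id must be unique in the ranked table")
  }
  n <- nrow(ranked_datasets)
  if (k > n) stopf("k (%d) exceeds the number of ranked datasets (%d)", k, n)
  fac <- as.character(ranked_datasets$factor)
  total <- table(fac)
  topk <- table(factor(fac[seq_len(k)], levels = names(total)))
  fc <- as.numeric(topk / k) / (as.numeric(total) / n)
  out <- data.frame(factor = names(total),
                    count_topk = as.integer(topk),
                    total_factor = as.integer(total),
                    k = as.integer(k), total_datasets = n,
                    fold_change = fc,
                    coenriched = fc > fc_threshold)
  out <- out[order(-out$fold_change, out$factor), ]
  rownames(out) <- NULL
  out
}

#' Cistrome-gene / DEG overlap enrichment
#'
#' Intersects a DEG set with a cistrome-annotated gene set, tests the
#' overlap with [hypergeom_enrichment()] against the supplied gene
#' universe, and reports the percentage of DEGs carrying a cistrome
#' annotation.
#'
#' @param degs,cistrome_genes,universe character vectors of gene ids;
#'   the two sets must be subsets of `universe`.
#' @param strict_tail passed to [hypergeom_enrichment()].
#' @param digits decimal places for the percentage.
#' @return one-row data.frame: enrichment columns plus percent_overlap.
#' @export
cistrome_gene_overlap <- function(degs, cistrome_genes, universe,
                                  strict_tail = FALSE, digits = 1) {
  if (length(universe) == 0) stopf("gene universe is empty")
  degs <- unique(degs); cistrome_genes <- unique(cistrome_genes)
  universe <- unique(universe)
  if (!all(degs %in% universe) || !all(cistrome_genes %in% universe)) {
    stopf("degs and cistrome_genes must be subsets of the universe")
  }
  k <- length(intersect(degs, cistrome_genes))
  res <- hypergeom_enrichment(k, length(degs), length(cistrome_genes),
                              length(universe), strict_tail = strict_tail)
  res$percent_overlap <- percent_overlap(k, length(degs) - k, digits = digits)
  res
}
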