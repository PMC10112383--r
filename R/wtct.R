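#' Distance-decay weight for a peak:gene link
#'
#' Exponential half-life decay on the midpoint-to-TSS distance:
#' `exp(-ln(2) * |distance| / decay)`, so a peak exactly `decay` bp from
#' the TSS contributes half the weight of a TSS-overlapping peak. Links
#' with `zone == "within"` always weigh 1.
#'
#' @param distance signed midpoint-to-TSS distances (bp).
#' @param zone link zones (`"within"` forces weight 1); optional.
#' @param decay half-life distance in bp (> 0); default 10 kb, the
#'   promoter-proximal cutoff.
#' @return weights in (0, 1].
#' @export
peak_weight <- function(distance, zone = NULL, decay = 10000) {
  if (decay <= 0) stopf("decay must be > 0")
  w <- exp(-log(2) * abs(distance) / decay)
  if (!is.null(zone)) w[zone == "within"] <- 1
  w
}

#' Weighted cistrome-transcriptome (wt-C-T) score per gene
#'
#' For each differentially expressed gene with at least one linked peak,
#' sums the significance of its peaks within the annotation window and
#' multiplies by the gene's absolute log2 fold change. The weighted
#' variant down-weights distal peaks (scheme `"decay"`, the default, via
#' [peak_weight()]; scheme `"zone_proportion"` instead weights each peak
#' by the fraction of the gene's links sharing its zone class, with
#' `within` counted as proximal). Peak significances are capped so a
#' single extreme region cannot dominate a gene's sum.
#'
#' @param links link table from [annotate_peaks()].
#' @param peaks peak `GRanges` carrying the `significance` column, or a
#'   data.frame with peak_id and significance.
#' @param degs DEG data.frame with gene_id and log2fc (typically the
#'   output of [filter_deg()]).
#' @param decay half-life for the decay scheme (bp).
#' @param sig_cap upper cap applied to each peak's significance.
#' @param weight_scheme `"decay"` or `"zone_proportion"`.
#' @return data.frame: gene_id, n_peaks, peak_sig_sum, absfc,
#'   weighted_score, unweighted_score.
#' @export
wtct_scores <- function(links, peaks, degs, decay = 10000, sig_cap = 50,
                        weight_scheme = c("decay", "zone_proportion")) {
  weight_scheme <- match.arg(weight_scheme)
  assert_columns(degs, c("gene_id", "log2fc"), "DEG table")
  if (methods::is(peaks, "GRanges")) {
    sig_tab <- data.frame(peak_id = S4Vectors::mcols(peaks)$id,
                          significance = S4Vectors::mcols(peaks)$significance)
  } else {
    assert_columns(peaks, c("peak_id", "significance"), "peak table")
    sig_tab <- peaks
  }
  lk <- links[links$gene_id %in% degs$gene_id, , drop = FALSE]
  empty <- data.frame(gene_id = character(), n_peaks = integer(),
                      peak_sig_sum = numeric(), absfc = numeric(),
                      weighted_score = numeric(), unweighted_score = numeric())
  if (nrow(lk) == 0) return(empty)
  sig <- sig_tab$significance[match(lk$peak_id, sig_tab$peak_id)]
  if (anyNA(sig)) stopf("link table references peaks with no significance")
  sig <- pmin(sig, sig_cap)
  w <- switch(weight_scheme,
    decay = peak_weight(lk$distance, lk$zone, decay),
    zone_proportion = {
      zclass <- ifelse(lk$zone == "distal", "distal", "proximal")
      frac <- stats::ave(seq_len(nrow(lk)),
                         paste(lk$gene_id, zclass, sep = "\r"),
                         FUN = length) /
        stats::ave(seq_len(nrow(lk)), lk$gene_id, FUN = length)
      frac
    })
  agg <- stats::aggregate(cbind(sig_sum = sig, wsig_sum = sig * w,
                                n = rep(1L, nrow(lk))),
                          by = list(gene_id = lk$gene_id), FUN = sum)
  absfc <- abs(degs$log2fc[match(agg$gene_id, degs$gene_id)])
  out <- data.frame(gene_id = agg$gene_id,
                    n_peaks = as.integer(agg$n),
                    peak_sig_sum = agg$sig_sum,
                    absfc = absfc,
                    weighted_score = absfc * agg$wsig_sum,
                    unweighted_score = absfc * agg$sig_sum)
  out <- out[order(-out$weighted_score, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Aggregate wt-C-T scores per stratum with a permutation null
#'
#' Strata are labels attached to genes (cell line, condition, chromatin
#' state of the linking peaks); a gene may appear under several labels.
#' The statistic per stratum is the mean weighted score; significance
#' comes from shuffling labels across the (gene, label) rows, which
#' preserves the pooled score distribution. The one-sided empirical p is
#' `(1 + #(null mean >= observed)) / (draws + 1)`. With a single stratum
#' every permutation reproduces the observed mean, so p = 1.
#'
#' @param results per-gene table from [wtct_scores()].
#' @param strata data.frame with gene_id and label.
#' @param null_draws number of label permutations (>= 100).
#' @param seed RNG seed (required: permutation results must be
#'   reproducible).
#' @param score_col which score to aggregate.
#' @return data.frame: label, n_genes, mean_score, total_score,
#'   null_mean, empirical_p (NA for empty strata).
#' @export
aggregate_wtct <- function(results, strata, null_draws = 10000, seed,
                           score_col = "weighted_score") {
  if (missing(seed)) stopf("seed is required for the permutation null")
  if (null_draws < 100) stopf("null_draws must be >= 100")
  assert_columns(strata, c("gene_id", "label"), "strata map")
  sc <- results[[score_col]][match(strata$gene_id, results$gene_id)]
  keep <- !is.na(sc)
  lab <- factor(strata$label[keep])
  sc <- sc[keep]
  all_labels <- unique(strata$label)
  obs_mean <- tapply(sc, lab, mean)
  obs_tot <- tapply(sc, lab, sum)
  nlab <- nlevels(lab)
  null_means <- matrix(NA_real_, null_draws, nlab,
                       dimnames = list(NULL, levels(lab)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(null_draws)) {
    null_means[b, ] <- tapply(sc, lab[sample.int(length(lab))], mean)
  }
  ge <- colSums(sweep(null_means, 2, obs_mean, ">=" ), na.rm = TRUE)
  p <- (1 + ge) / (null_draws + 1)
  pick <- function(v, default = NA_real_) {
    r <- rep(default, length(all_labels))
    m <- match(levels(lab), all_labels)
    r[m] <- as.numeric(v)
    r
  }
  out <- data.frame(label = all_labels,
                    n_genes = as.integer(pick(table(lab), default = 0)),
                    mean_score = pick(obs_mean),
                    total_score = pick(obs_tot),
                    null_mean = pick(colMeans(null_means)),
                    empirical_p = pick(p))
  out$empirical_p[out$n_genes == 0] <- NA_real_
  rownames(out) <- NULL
  out
}

# Save/restore the global RNG state so seeded routines do not perturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
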