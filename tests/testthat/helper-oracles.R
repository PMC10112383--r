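# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the package's interval machinery so the
# oracle-equivalence tests compare two genuinely different routes.

# Random region set in BED convention (plain data.frame, no GRanges).
random_regions_df <- function(n, n_chroms = 3, chrom_len = 1e5,
                              len_range = c(50, 2000), prefix = "r") {
  chrom <- sprintf("chr%d", sample.int(n_chroms, n, replace = TRUE))
  len <- round(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n, 0, chrom_len - len))
  data.frame(chrom = chrom, start = start, end = start + len,
             id = sprintf("%s%04d", prefix, seq_len(n)))
}

df_to_peaks <- function(df, significance = NULL) {
  peak_ranges(df$chrom, df$start, df$end, df$id, significance = significance)
}

# >= 1 bp overlap of two BED intervals, by arithmetic on raw coordinates.
bed_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & pmax(s1, s2) < pmin(e1, e2)
}

# gap in bp between two non-overlapping BED intervals on one chromosome
bed_gap <- function(s1, e1, s2, e2) {
  ifelse(e1 <= s2, s2 - e1, ifelse(e2 <= s1, s1 - e2, 0))
}

# Exhaustive double loop over all (peak, gene) pairs: the annotation
# oracle. Returns sorted peak_id/gene_id/distance/zone rows.
annotate_oracle <- function(pk, gn, window = 1e5, proximal = 1e4) {
  rows <- list()
  for (i in seq_len(nrow(pk))) {
    for (j in seq_len(nrow(gn))) {
      if (pk$chrom[i] != gn$chrom[j]) next
      ov <- bed_overlap(pk$chrom[i], pk$start[i], pk$end[i],
                        gn$chrom[j], gn$start[j], gn$end[j])
      gap <- bed_gap(pk$start[i], pk$end[i], gn$start[j], gn$end[j])
      linked <- ov || (window > 0 && gap <= window)
      if (!linked) next
      mid <- floor((pk$start[i] + pk$end[i]) / 2)
      tss <- if (gn$strand[j] == "+") gn$start[j] else gn$end[j] - 1
      d <- if (gn$strand[j] == "-") tss - mid else mid - tss
      zone <- if (ov) "within" else if (abs(d) <= proximal) "proximal" else "distal"
      rows[[length(rows) + 1]] <- data.frame(
        peak_id = pk$id[i], gene_id = gn$gene_id[j],
        distance = d, zone = zone)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

# Venn membership by quadratic all-pairs scan over raw coordinates.
venn_oracle <- function(dfs) {
  labs <- names(dfs)
  do.call(rbind, lapply(labs, function(li) {
    a <- dfs[[li]]
    comp <- vapply(seq_len(nrow(a)), function(i) {
      m <- vapply(labs, function(lj) {
        if (lj == li) return(TRUE)
        b <- dfs[[lj]]
        any(bed_overlap(a$chrom[i], a$start[i], a$end[i],
                        b$chrom, b$start, b$end))
      }, logical(1))
      paste(labs[m], collapse = "&")
    }, character(1))
    data.frame(set = li, id = a$id, compartment = comp)
  }))
}

# Per-base chromatin-state counting oracle.
state_oracle <- function(pk, st, state_order) {
  vapply(seq_len(nrow(pk)), function(i) {
    bases <- pk$start[i]:(pk$end[i] - 1)
    lab <- rep(NA_character_, length(bases))
    for (j in seq_len(nrow(st))) {
      if (st$chrom[j] != pk$chrom[i]) next
      inside <- bases >= st$start[j] & bases < st$end[j]
      lab[inside] <- st$state[j]
    }
    cnt <- table(factor(lab, levels = state_order))
    if (sum(cnt) == 0) return(NA_character_)
    state_order[which.max(cnt)]  # which.max takes the first max: priority order
  }, character(1))
}

# Exhaustive hypergeometric upper tail by enumerating all draws.
hypergeom_enum <- function(hits, set_size, category_size, universe) {
  draws <- utils::combn(universe, set_size)
  mean(apply(draws, 2, function(s) sum(s <= category_size) >= hits))
}

# Toy gene model on one chromosome for hand-built cases.
toy_genes <- function() {
  gene_ranges(chrom = c("chr1", "chr1", "chr2"),
              start = c(1000, 50000, 2000),
              end = c(10000, 80000, 9000),
              gene_id = c("gA", "gB", "gC"),
              strand = c("+", "-", "+"))
}
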