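#' Configuration for the synthetic-data generator
#'
#' Builds the fully-validated parameter list the generators consume.
#' Defaults describe a desk-scale regulatory landscape: a two-chromosome
#' 40-Mb genome carrying 500 non-overlapping genes of which 20% respond
#' to the stimulus; two peak sets (conditions) of 2,000 regions each,
#' 70% placed within the 100-kb annotation window of responsive genes;
#' heavy-tailed gamma peak significances; DEG tables with
#' Benjamini-Hochberg adjusted p-values; a two-condition NES table whose
#' shape mirrors a divergent gene-set landscape (211 terms, 135 with
#' delta above 3); and a two-group expression cohort of 36 samples per
#' group in which targets depend linearly on a TF and on one planted
#' coregulator in group A only.
#'
#' @param seed integer RNG seed; mandatory, every generator is a pure
#'   function of the config.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes; `gene_length_range` their size range.
#' @param frac_responsive fraction of genes marked stimulus-responsive.
#' @param n_peaks regions per condition; `peak_length_range` their size.
#' @param frac_peaks_near_genes fraction of each condition's peaks placed
#'   within `window` bp of a responsive gene.
#' @param window annotation window emulated by the placement (bp).
#' @param peak_sig_shape,peak_sig_scale gamma parameters for region
#'   significances (`-log10` adjusted p).
#' @param conditions named list of per-condition overrides, each a list
#'   with any of `sig_scale` (multiplies significances) and
#'   `near_spread` (max |midpoint - TSS| for near-gene placement, bp).
#' @param deg_effect mean |log2FC| of true DEGs; `frac_true_deg` equals
#'   `frac_responsive` unless overridden.
#' @param noise_sd residual noise scale shared by the DEG and
#'   expression generators.
#' @param nes_n_terms,nes_frac_opposite,nes_delta_scale NES table shape.
#' @param expr_n_samples samples per group in the expression cohort.
#' @param n_targets,n_coregulators,n_background expression matrix genes:
#'   planted targets, coregulator candidates (only the first is
#'   planted), and unrelated background genes.
#' @param coreg_beta named per-group planted coregulator coefficient.
#' @param tf_effect per-target TF coefficient.
#' @param tf_coreg_cor correlation between TF and the planted
#'   coregulator (0 = independent regulators).
#' @param states chromatin-state vocabulary used to tile the genome;
#'   `state_mean_len` the mean segment length (bp).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chroms = 2, chrom_length = 2e7,
                       n_genes = 500, gene_length_range = c(5e3, 4e4),
                       frac_responsive = 0.2,
                       n_peaks = 2000, peak_length_range = c(200, 600),
                       frac_peaks_near_genes = 0.7, window = 1e5,
                       peak_sig_shape = 1.2, peak_sig_scale = 2,
                       conditions = list(A = list(), B = list()),
                       deg_effect = 1.0, frac_true_deg = frac_responsive,
                       noise_sd = 0.5,
                       nes_n_terms = 211, nes_frac_opposite = 135 / 211,
                       nes_delta_scale = 3,
                       expr_n_samples = 36, n_targets = 20,
                       n_coregulators = 6, n_background = 30,
                       coreg_beta = c(A = 0.6, B = 0),
                       tf_effect = 0.6, tf_coreg_cor = 0,
                       states = c("Promoter", "Enhancer", "Transcribed",
                                  "Bivalent", "Polycomb", "Quiescent"),
                       state_mean_len = 5e3) {
  if (missing(seed)) stopf("sim_config requires a seed")
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 1, n_peaks >= 1,
              frac_responsive > 0, frac_responsive <= 1,
              frac_peaks_near_genes >= 0, frac_peaks_near_genes <= 1,
              frac_true_deg >= 0, frac_true_deg <= 1,
              nes_frac_opposite >= 0, nes_frac_opposite <= 1,
              expr_n_samples >= 4, noise_sd > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a genome, gene models, per-condition peak sets, and a
#' chromatin-state segmentation
#'
#' Genes are placed uniformly without overlap (error if they cannot
#' fit). In each condition, `frac_peaks_near_genes` of the peaks are
#' placed so their gap to a randomly chosen responsive gene's span is at
#' most `window` (hence each is guaranteed at least one annotation
#' link); the remainder land uniformly. Significances are gamma draws;
#' each condition may rescale them (`sig_scale`) or tighten placement
#' around the TSS (`near_spread`). States tile every chromosome with
#' exponential-length segments.
#'
#' @param cfg a [sim_config()].
#' @return list: genes (`GRanges`), responsive (gene ids), peaks (named
#'   list of peak `GRanges` per condition), states (`GRanges`).
#' @export
simulate_genome_and_peaks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  gene_chrom <- sort(sample(rep_len(seq_len(cfg$n_chroms), cfg$n_genes)))
  genes <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    n <- sum(gene_chrom == ci)
    if (n == 0) return(NULL)
    len <- round(stats::runif(n, cfg$gene_length_range[1],
                              cfg$gene_length_range[2]))
    free <- cfg$chrom_length - sum(len)
    if (free < 0) stopf("genome too small to place %d genes without overlap", n)
    gaps <- diff(c(0, sort(stats::runif(n, 0, free))))
    start <- cumsum(gaps) + cumsum(c(0, len[-n]))
    data.frame(chrom = chroms[ci], start = floor(start),
               end = floor(start) + len)
  }))
  gene_id <- sprintf("gene_%03d", seq_len(cfg$n_genes))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_gr <- gene_ranges(genes$chrom, genes$start, genes$end, gene_id, strand)
  responsive <- sort(sample(gene_id, round(cfg$frac_responsive * cfg$n_genes)))

  resp_idx <- match(responsive, gene_id)
  peaks <- lapply(names(cfg$conditions), function(cond) {
    par <- cfg$conditions[[cond]]
    sig_scale <- par$sig_scale %||% 1
    spread <- par$near_spread %||% cfg$window
    n_near <- round(cfg$frac_peaks_near_genes * cfg$n_peaks)
    len <- round(stats::runif(cfg$n_peaks, cfg$peak_length_range[1],
                              cfg$peak_length_range[2]))
    chrom <- character(cfg$n_peaks); start <- numeric(cfg$n_peaks)
    if (n_near > 0) {
      gi <- resp_idx[sample.int(length(resp_idx), n_near, replace = TRUE)]
      gs <- genes$start[gi]; ge <- genes$end[gi]
      tss <- S4Vectors::mcols(gene_gr)$tss[gi]
      # place the midpoint within `spread` of the TSS, then clamp into
      # the linkable interval (gap to gene span <= window) and the chrom
      mid <- tss + round(stats::runif(n_near, -spread, spread))
      s <- mid - floor(len[seq_len(n_near)] / 2)
      lo <- pmax(0, gs - cfg$window - len[seq_len(n_near)] + 1)
      hi <- pmin(cfg$chrom_length - len[seq_len(n_near)], ge + cfg$window)
      s <- pmin(pmax(s, lo), hi)
      chrom[seq_len(n_near)] <- genes$chrom[gi]
      start[seq_len(n_near)] <- s
    }
    if (n_near < cfg$n_peaks) {
      i <- (n_near + 1):cfg$n_peaks
      chrom[i] <- chroms[sample.int(cfg$n_chroms, length(i), replace = TRUE)]
      start[i] <- floor(stats::runif(length(i), 0, cfg$chrom_length - len[i]))
    }
    sig <- stats::rgamma(cfg$n_peaks, shape = cfg$peak_sig_shape,
                         scale = cfg$peak_sig_scale * sig_scale)
    dir <- sample(c(-1L, 1L), cfg$n_peaks, replace = TRUE)
    peak_ranges(chrom, start, start + len,
                id = sprintf("%s_peak_%04d", cond, seq_len(cfg$n_peaks)),
                significance = sig, direction = dir)
  })
  names(peaks) <- names(cfg$conditions)

  states <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- 0; seg <- list()
    while (pos < cfg$chrom_length) {
      len <- max(200, round(stats::rexp(1, 1 / cfg$state_mean_len)))
      end <- min(pos + len, cfg$chrom_length)
      seg[[length(seg) + 1]] <- data.frame(
        chrom = ch, start = pos, end = end,
        state = sample(cfg$states, 1))
      pos <- end
    }
    do.call(rbind, seg)
  }))
  state_gr <- state_ranges(states$chrom, states$start, states$end,
                           states$state)
  list(genes = gene_gr, responsive = responsive, peaks = peaks,
       states = state_gr)
}

#' Simulate a differential-expression table
#'
#' Responsive genes receive |log2FC| centred on `deg_effect` and z-scores
#' centred on `3 * deg_effect / noise_sd` (an effect-over-standard-error
#' scale); all other genes are null. Two-sided normal p-values are
#' BH-adjusted so the `padj` semantics match what the filters expect.
#'
#' @param cfg a [sim_config()].
#' @param responsive_genes ids of true DEGs.
#' @param gene_ids all gene ids in the table.
#' @return data.frame: gene_id, log2fc, pvalue, padj, logpv, true_deg.
#' @export
simulate_deg_table <- function(cfg, responsive_genes, gene_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  n <- length(gene_ids)
  resp <- gene_ids %in% responsive_genes
  s <- sample(c(-1, 1), n, replace = TRUE)
  z <- stats::rnorm(n)
  mu <- 3 * cfg$deg_effect / cfg$noise_sd
  z[resp] <- s[resp] * abs(stats::rnorm(sum(resp), mean = mu))
  lfc <- stats::rnorm(n, 0, 0.1)
  lfc[resp] <- s[resp] * (cfg$deg_effect +
                            stats::rnorm(sum(resp), 0, cfg$noise_sd / 3))
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(gene_id = gene_ids, log2fc = lfc, pvalue = p,
             padj = stats::p.adjust(p, method = "BH"),
             logpv = -log10(p), true_deg = resp)
}

#' Simulate a two-condition NES table
#'
#' Plants exactly `round(nes_frac_opposite * nes_n_terms)` terms with a
#' sign-switched NES pair whose delta exceeds `nes_delta_scale`; the
#' remaining terms are concordant with delta below 1. All terms are
#' given per-condition FDRs under 0.1 so both-significant filtering
#' keeps the full table.
#'
#' @param cfg a [sim_config()].
#' @return data.frame: term, nes_a, nes_b, fdr_a, fdr_b, planted_opposite.
#' @export
simulate_nes_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2L)
  n <- cfg$nes_n_terms
  k <- round(cfg$nes_frac_opposite * n)
  opp <- seq_len(n) <= k
  s <- sample(c(-1, 1), n, replace = TRUE)
  nes_a <- s * stats::runif(n, 1.5, 3)
  nes_b <- numeric(n)
  nes_b[opp] <- nes_a[opp] - s[opp] *
    (cfg$nes_delta_scale + stats::runif(k, 0.3, 2))
  nes_b[!opp] <- nes_a[!opp] + stats::runif(n - k, -0.9, 0.9)
  ord <- sample.int(n)
  data.frame(term = sprintf("TERM_%04d", seq_len(n)),
             nes_a = nes_a[ord], nes_b = nes_b[ord],
             fdr_a = stats::runif(n, 1e-4, 0.09),
             fdr_b = stats::runif(n, 1e-4, 0.09),
             planted_opposite = opp[ord])
}

#' Simulate a two-group expression cohort with a planted coregulator
#'
#' The TF and all coregulators are standard normal across samples (the
#' first coregulator may correlate with the TF via `tf_coreg_cor`).
#' Each target is `tf_effect * TF + beta_g * COREG1 + N(0, noise_sd)`,
#' with `beta_g = coreg_beta[group]` — by default planted in group A
#' only. Per-sample covariates carry the threshold structure of the
#' emulated cohort: BMI with an obesity flag (> 30) and serum vitamin D
#' (25(OH)D3, ng/mL) with a deficiency flag (< 12).
#'
#' @param cfg a [sim_config()].
#' @return list: expr (samples x genes matrix), covariates (data.frame),
#'   tf, targets, coregulators (character vectors of column names).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 3L)
  groups <- names(cfg$coreg_beta)
  n <- cfg$expr_n_samples
  tf <- "TF"
  targets <- sprintf("TGT_%02d", seq_len(cfg$n_targets))
  coregs <- sprintf("COREG_%02d", seq_len(cfg$n_coregulators))
  bg <- sprintf("BG_%02d", seq_len(cfg$n_background))
  blocks <- lapply(groups, function(g) {
    x <- stats::rnorm(n)
    C <- matrix(stats::rnorm(n * cfg$n_coregulators), n)
    rho <- cfg$tf_coreg_cor
    if (rho != 0) C[, 1] <- rho * x + sqrt(1 - rho^2) * C[, 1]
    beta <- cfg$coreg_beta[[g]]
    Y <- vapply(seq_len(cfg$n_targets), function(i) {
      cfg$tf_effect * x + beta * C[, 1] + stats::rnorm(n, 0, cfg$noise_sd)
    }, numeric(n))
    B <- matrix(stats::rnorm(n * cfg$n_background), n)
    m <- cbind(x, Y, C, B)
    colnames(m) <- c(tf, targets, coregs, bg)
    rownames(m) <- sprintf("%s_s%02d", g, seq_len(n))
    m
  })
  expr <- do.call(rbind, blocks)
  bmi <- round(stats::rnorm(nrow(expr), 29, 4.5), 1)
  d3 <- round(pmax(stats::rnorm(nrow(expr), 18, 6), 3), 1)
  cov <- data.frame(sample = rownames(expr),
                    group = rep(groups, each = n),
                    bmi = bmi, obese = bmi > 30,
                    serum_d3 = d3, d3_low = d3 < 12)
  list(expr = expr, covariates = cov, tf = tf, targets = targets,
       coregulators = coregs)
}

#' Materialise a complete synthetic fixture directory
#'
#' Runs every generator and writes the exact formats the readers
#' consume: `genes.gff3`, `peaks_<condition>.bed`, `states.bed`,
#' `deg.tsv`, `nes.tsv`, `expression.tsv`, `covariates.tsv`,
#' `targets.txt`, `coregulators.txt`, `responsive_genes.txt`. Identical
#' configs produce byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_all <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gp <- simulate_genome_and_peaks(cfg)
  deg <- simulate_deg_table(cfg, gp$responsive,
                            S4Vectors::mcols(gp$genes)$gene_id)
  nes <- simulate_nes_tables(cfg)
  ex <- simulate_expression(cfg)
  paths <- c(genes = file.path(dir, "genes.gff3"),
             states = file.path(dir, "states.bed"),
             deg = file.path(dir, "deg.tsv"),
             nes = file.path(dir, "nes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             targets = file.path(dir, "targets.txt"),
             coregulators = file.path(dir, "coregulators.txt"),
             responsive = file.path(dir, "responsive_genes.txt"))
  write_genes(gp$genes, paths["genes"])
  write_states(gp$states, paths["states"])
  for (cond in names(gp$peaks)) {
    p <- file.path(dir, sprintf("peaks_%s.bed", cond))
    write_peaks(gp$peaks[[cond]], p)
    paths[paste0("peaks_", cond)] <- p
  }
  utils::write.table(deg, paths["deg"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nes, paths["nes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  em <- data.frame(sample = rownames(ex$expr), ex$expr,
                   check.names = FALSE)
  utils::write.table(em, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ex$covariates, paths["covariates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ex$targets, paths["targets"])
  writeLines(ex$coregulators, paths["coregulators"])
  writeLines(gp$responsive, paths["responsive"])
  invisible(paths)
}
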