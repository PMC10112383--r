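#' Pipeline configuration
#'
#' Assembles the configuration consumed by the `run_*()` stages, from an
#' optional YAML file plus in-call overrides. Defaults carry the
#' conventional analysis constants: 100-kb annotation window, 10-kb
#' proximal cutoff and decay half-life, DEG thresholds (`logpv_min` 1,
#' `absfc_min` 0.37, `padj_max` 0.1), delta-NES threshold 3, top-200 /
#' 1.2-fold factor co-enrichment, and 10-kb distance bins. Any
#' stochastic stage refuses to run without a seed.
#'
#' @param path optional YAML file; keys mirror the argument names.
#' @param ... overrides (highest precedence).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    peaks = NULL, genes = NULL, states = NULL, deg = NULL, nes = NULL,
    motifs_reference = NULL, motifs = NULL,
    expression = NULL, covariates = NULL, targets = NULL,
    coregulators = NULL, tf = "TF",
    out_dir = "cistromeCT_out",
    window = 100000, proximal_cutoff = 10000, nearest_only = FALSE,
    decay = 10000, sig_cap = 50, weight_scheme = "decay",
    bin_width = 10000,
    logpv_min = 1, absfc_min = 0.37, use_padj = FALSE, padj_max = 0.1,
    delta_threshold = 3, require_both_significant = TRUE, fdr_max = 0.1,
    require_sign_switch = FALSE,
    k = 200, fc_threshold = 1.2, strict_tail = FALSE,
    null_draws = 10000, permutations = 1000, seed = NULL)
  cfg <- defaults
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    unknown <- setdiff(names(y), names(defaults))
    if (length(unknown)) stopf("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown)) stopf("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pipeline_config")
}

path_keys <- c("peaks", "genes", "states", "deg", "nes", "motifs_reference",
               "motifs", "expression", "covariates", "targets",
               "coregulators", "out_dir")

provenance_of <- function(config) {
  # hash the analysis parameters only: where files live must not change
  # what the reports say
  params <- unclass(config)[setdiff(names(config), path_keys)]
  list(tool = paste0("cistromeCT ",
                     as.character(utils::packageVersion("cistromeCT"))),
       config_hash = config_hash(params),
       seed = config$seed %||% "none")
}

require_seed <- function(config, stage) {
  if (is.null(config$seed)) stopf("%s is stochastic: config$seed is required",
                                  stage)
  invisible(config$seed)
}

out_path <- function(config, name) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$out_dir, name)
}

log_info <- function(fmt, ...) message(sprintf(fmt, ...))

#' Pipeline stages
#'
#' Thin orchestration over the analysis functions: each stage reads the
#' files named in the config, runs one module, logs record counts to
#' stderr and writes TSV reports (with a provenance header: package
#' version, config hash, seed) under `out_dir`. Inputs are never
#' modified; identical config and seed give byte-identical reports.
#'
#' `run_simulate` materialises a synthetic fixture directory and points
#' the config's input paths at it, so
#' `run_annotate(run_simulate(config))` onwards exercises the full
#' pipeline without external data.
#'
#' @param config a [pipeline_config()].
#' @param sim_cfg for `run_simulate`, an optional [sim_config()]
#'   (default: one built from `config$seed`).
#' @return the (possibly updated) config for `run_simulate`; otherwise
#'   the written report paths, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config, sim_cfg = NULL) {
  require_seed(config, "simulate")
  if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed)
  dir <- out_path(config, "fixture")
  paths <- simulate_all(sim_cfg, dir)
  log_info("simulate: wrote %d files under %s", length(paths), dir)
  peak_paths <- paths[startsWith(names(paths), "peaks_")]
  names(peak_paths) <- sub("^peaks_", "", names(peak_paths))
  config$peaks <- as.list(peak_paths)
  config$genes <- unname(paths["genes"])
  config$states <- unname(paths["states"])
  config$deg <- unname(paths["deg"])
  config$nes <- unname(paths["nes"])
  config$expression <- unname(paths["expression"])
  config$covariates <- unname(paths["covariates"])
  config$targets <- unname(paths["targets"])
  config$coregulators <- unname(paths["coregulators"])
  config
}

#' @rdname pipeline
#' @export
run_annotate <- function(config) {
  if (is.null(config$peaks) || is.null(config$genes)) {
    stopf("annotate needs config$peaks and config$genes")
  }
  genes <- read_genes(config$genes)
  states <- if (!is.null(config$states)) read_states(config$states)
  prov <- provenance_of(config)
  out <- character()
  for (cond in names(config$peaks)) {
    peaks <- read_peaks(config$peaks[[cond]])
    links <- annotate_peaks(peaks, genes, window = config$window,
                            proximal_cutoff = config$proximal_cutoff,
                            nearest_only = config$nearest_only)
    if (!is.null(states)) {
      links <- add_link_states(links, assign_chrom_states(peaks, states))
    }
    log_info("annotate[%s]: %d peaks, %d genes -> %d links",
             cond, length(peaks), length(genes), nrow(links))
    p <- out_path(config, sprintf("links_%s.tsv", cond))
    write_tsv_report(links, p, prov)
    bins <- bin_link_distances(links, bin_width = config$bin_width,
                               range = c(-config$window, config$window))
    pb <- out_path(config, sprintf("link_distance_bins_%s.tsv", cond))
    write_tsv_report(bins, pb, prov)
    out <- c(out, p, pb)
  }
  invisible(out)
}

#' @rdname pipeline
#' @export
run_enrich <- function(config) {
  if (is.null(config$deg)) stopf("enrich needs config$deg")
  genes <- read_genes(config$genes)
  universe <- S4Vectors::mcols(genes)$gene_id
  deg_tab <- read_deg_table(config$deg)
  degs <- filter_deg(deg_tab, logpv_min = config$logpv_min,
                     absfc_min = config$absfc_min,
                     use_padj = config$use_padj,
                     padj_max = config$padj_max)
  log_info("enrich: DEG filter kept %d / %d records", nrow(degs),
           nrow(deg_tab))
  prov <- provenance_of(config)
  rows <- lapply(names(config$peaks), function(cond) {
    links <- read_tsv_report(out_path(config, sprintf("links_%s.tsv", cond)))
    cg <- unique(links$gene_id)
    res <- cistrome_gene_overlap(degs$gene_id, cg, universe,
                                 strict_tail = config$strict_tail)
    log_info("enrich[%s]: %d cistrome genes, overlap %d, logPval %.2f",
             cond, length(cg), res$overlap_k, res$logpv)
    cbind(cistrome = cond, res)
  })
  p <- out_path(config, "cistrome_deg_enrichment.tsv")
  write_tsv_report(do.call(rbind, rows), p, prov)
  invisible(p)
}

#' @rdname pipeline
#' @export
run_wtct <- function(config) {
  require_seed(config, "wtct")
  deg_tab <- read_deg_table(config$deg)
  degs <- filter_deg(deg_tab, logpv_min = config$logpv_min,
                     absfc_min = config$absfc_min,
                     use_padj = config$use_padj, padj_max = config$padj_max)
  prov <- provenance_of(config)
  out <- character()
  for (cond in names(config$peaks)) {
    peaks <- read_peaks(config$peaks[[cond]])
    links <- read_tsv_report(out_path(config, sprintf("links_%s.tsv", cond)))
    sc <- wtct_scores(links, peaks, degs, decay = config$decay,
                      sig_cap = config$sig_cap,
                      weight_scheme = config$weight_scheme)
    log_info("wtct[%s]: scored %d genes", cond, nrow(sc))
    p <- out_path(config, sprintf("wtct_genes_%s.tsv", cond))
    write_tsv_report(sc, p, prov)
    out <- c(out, p)
    if (!all(is.na(links$state))) {
      strata <- unique(links[!is.na(links$state), c("gene_id", "state")])
      names(strata)[2] <- "label"
      agg <- aggregate_wtct(sc, strata, null_draws = config$null_draws,
                            seed = config$seed)
      pa <- out_path(config, sprintf("wtct_strata_%s.tsv", cond))
      write_tsv_report(agg, pa, prov)
      out <- c(out, pa)
    }
  }
  invisible(out)
}

#' @rdname pipeline
#' @export
run_delta_nes <- function(config) {
  if (is.null(config$nes)) stopf("delta-nes needs config$nes")
  nes <- read_nes_table(config$nes)
  res <- delta_nes(nes, delta_threshold = config$delta_threshold,
                   require_both_significant = config$require_both_significant,
                   fdr_max = config$fdr_max,
                   require_sign_switch = config$require_sign_switch)
  log_info("delta-nes: %d terms, %d opposite (%.1f%%)",
           res$summary$n_terms, res$summary$n_opposite,
           res$summary$percent_opposite)
  prov <- provenance_of(config)
  p1 <- out_path(config, "delta_nes.tsv")
  p2 <- out_path(config, "delta_nes_summary.tsv")
  write_tsv_report(res$records, p1, prov)
  write_tsv_report(res$summary, p2, prov)
  invisible(c(p1, p2))
}

#' @rdname pipeline
#' @export
run_delta_motif <- function(config) {
  if (is.null(config$motifs_reference) || is.null(config$motifs)) {
    stopf("delta-motif needs config$motifs_reference and config$motifs")
  }
  ref <- read_tsv_report(config$motifs_reference)
  prov <- provenance_of(config)
  out <- character()
  conds <- lapply(config$motifs, read_tsv_report)
  deltas <- delta_motif(ref, conds)
  for (cond in names(deltas)) {
    p <- out_path(config, sprintf("delta_motif_%s.tsv", cond))
    write_tsv_report(deltas[[cond]], p, prov)
    log_info("delta-motif[%s]: %d motifs", cond, nrow(deltas[[cond]]))
    out <- c(out, p)
  }
  invisible(out)
}

#' @rdname pipeline
#' @export
run_partialcorr <- function(config) {
  require_seed(config, "partialcorr")
  expr <- read_expression(config$expression)
  cov <- utils::read.delim(config$covariates, comment.char = "#",
                           stringsAsFactors = FALSE)
  targets <- read_gene_list(config$targets)
  coregs <- read_gene_list(config$coregulators)
  groups <- sort(unique(cov$group))
  prov <- provenance_of(config)
  res <- lapply(groups, function(g) {
    idx <- which(cov$group == g)
    screen <- delta_corr_screen(expr[idx, , drop = FALSE], config$tf,
                                targets, coregs,
                                permutations = config$permutations,
                                seed = config$seed)
    log_info("partialcorr[%s]: %d samples, %d coregulators screened",
             g, length(idx), nrow(screen))
    p <- out_path(config, sprintf("delta_corr_%s.tsv", g))
    write_tsv_report(screen, p, prov)
    screen
  })
  out <- out_path(config, sprintf("delta_corr_%s.tsv", groups))
  if (length(groups) == 2) {
    contrast <- group_contrast(res[[1]], res[[2]], labels = groups)
    p <- out_path(config, "delta_corr_contrast.tsv")
    write_tsv_report(contrast, p, prov)
    out <- c(out, p)
  }
  invisible(out)
}
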