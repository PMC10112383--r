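toy_links <- function(dist, zone, gene = "g1", peak = NULL) {
  n <- length(dist)
  data.frame(peak_id = peak %||% sprintf("p%d", seq_len(n)),
             gene_id = rep_len(gene, n), chrom = "chr1",
             distance = dist, zone = zone, state = NA_character_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("peak weight is an exponential half-life in distance", {
  expect_equal(peak_weight(0), 1.0)
  expect_equal(peak_weight(10000, decay = 10000), 0.5)
  expect_equal(peak_weight(20000, decay = 10000), 0.25)
  expect_equal(peak_weight(-10000, decay = 10000), 0.5)
  expect_equal(peak_weight(50000, zone = "within", decay = 10000), 1.0)
  expect_error(peak_weight(0, decay = 0), "decay")
})

test_that("gene scores are summed significance times |log2FC|", {
  # one peak, significance 2, |FC| 1.5, weight 1 -> 3
  sc <- wtct_scores(toy_links(0, "within"),
                    data.frame(peak_id = "p1", significance = 2),
                    data.frame(gene_id = "g1", log2fc = -1.5))
  expect_equal(sc$weighted_score, 3.0)
  expect_equal(sc$unweighted_score, 3.0)
  # |FC| = 0 -> score 0 regardless of peaks
  sc0 <- wtct_scores(toy_links(c(0, 5000), c("within", "proximal")),
                     data.frame(peak_id = c("p1", "p2"),
                                significance = c(9, 9)),
                     data.frame(gene_id = "g1", log2fc = 0))
  expect_equal(sc0$weighted_score, 0)
  # two peaks sig {1,3}, weights {1, 0.5}, |FC| 2 -> weighted 5, unweighted 8
  sc2 <- wtct_scores(toy_links(c(0, 10000), c("within", "distal")),
                     data.frame(peak_id = c("p1", "p2"),
                                significance = c(1, 3)),
                     data.frame(gene_id = "g1", log2fc = 2),
                     decay = 10000)
  expect_equal(sc2$weighted_score, 5.0)
  expect_equal(sc2$unweighted_score, 8.0)
  expect_equal(sc2$n_peaks, 2L)
  # genes without links are not emitted
  scx <- wtct_scores(toy_links(0, "within"),
                     data.frame(peak_id = "p1", significance = 2),
                     data.frame(gene_id = c("g1", "lonely"),
                                log2fc = c(1, 5)))
  expect_equal(scx$gene_id, "g1")
})

test_that("weighted <= unweighted, linearity, and the decay -> Inf limit", {
  set.seed(23)
  n <- 300
  links <- toy_links(round(runif(n, -9e4, 9e4)),
                     sample(c("proximal", "distal", "within"), n, TRUE),
                     gene = sample(sprintf("g%02d", 1:30), n, TRUE))
  sig <- data.frame(peak_id = links$peak_id, significance = rgamma(n, 1.2, 0.5))
  degs <- data.frame(gene_id = sprintf("g%02d", 1:30),
                     log2fc = rnorm(30, 0, 1.2))
  sc <- wtct_scores(links, sig, degs)
  expect_true(all(sc$weighted_score <= sc$unweighted_score + 1e-12))
  expect_true(all(sc$weighted_score >= 0))
  # doubling every peak significance doubles every score
  sig2 <- transform(sig, significance = significance * 2)
  sc2 <- wtct_scores(links, sig2, degs, sig_cap = Inf)
  sc1 <- wtct_scores(links, sig, degs, sig_cap = Inf)
  expect_equal(sc2$weighted_score, 2 * sc1$weighted_score)
  # peak input order does not matter
  perm <- sample.int(n)
  sc3 <- wtct_scores(links[perm, ], sig[perm, ], degs)
  expect_equal(sc3[order(sc3$gene_id), ], sc[order(sc$gene_id), ],
               ignore_attr = TRUE)
  # infinite half-life: weighted equals unweighted
  sc_inf <- wtct_scores(links, sig, degs, decay = 1e15)
  expect_equal(sc_inf$weighted_score, sc_inf$unweighted_score,
               tolerance = 1e-9)
  # significance cap bounds single-peak dominance
  sig_big <- transform(sig, significance = significance + 1000)
  sc_cap <- wtct_scores(links, sig_big, degs, sig_cap = 50)
  expect_true(all(sc_cap$peak_sig_sum <= 50 * sc_cap$n_peaks))
})

test_that("zone-proportion weighting stays within [0, 1] of unweighted", {
  set.seed(29)
  links <- toy_links(round(runif(60, -9e4, 9e4)),
                     sample(c("proximal", "distal", "within"), 60, TRUE),
                     gene = sample(c("g1", "g2"), 60, TRUE))
  sig <- data.frame(peak_id = links$peak_id, significance = rgamma(60, 2, 1))
  degs <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1, -2))
  sc <- wtct_scores(links, sig, degs, weight_scheme = "zone_proportion")
  expect_true(all(sc$weighted_score <= sc$unweighted_score + 1e-12))
  expect_true(all(sc$weighted_score > 0))
})

test_that("aggregate wt-C-T: one stratum gives p = 1, permutation is seeded", {
  res <- data.frame(gene_id = sprintf("g%d", 1:50),
                    weighted_score = rgamma(50, 2, 1))
  strata <- data.frame(gene_id = res$gene_id, label = "all")
  agg <- aggregate_wtct(res, strata, null_draws = 200, seed = 1)
  expect_equal(agg$empirical_p, 1)
  expect_equal(agg$n_genes, 50L)
  # identical seeds agree; the result is a deterministic function of seed
  strata2 <- data.frame(gene_id = res$gene_id,
                        label = rep(c("a", "b"), 25))
  a1 <- aggregate_wtct(res, strata2, null_draws = 300, seed = 4)
  a2 <- aggregate_wtct(res, strata2, null_draws = 300, seed = 4)
  expect_equal(a1, a2)
  # empty stratum reported with n 0 and absent p
  strata3 <- rbind(strata2, data.frame(gene_id = "absent_gene", label = "c"))
  a3 <- aggregate_wtct(res, strata3, null_draws = 200, seed = 4)
  expect_equal(a3$n_genes[a3$label == "c"], 0L)
  expect_true(is.na(a3$empirical_p[a3$label == "c"]))
  expect_error(aggregate_wtct(res, strata2, null_draws = 200), "seed")
})

test_that("planted score inflation in one stratum is detected", {
  set.seed(77)
  mk <- function(seed) {
    set.seed(seed)
    data.frame(gene_id = sprintf("g%d", 1:400),
               weighted_score = c(rgamma(200, 1.2, scale = 2),
                                  2 * rgamma(200, 1.2, scale = 2)),
               stringsAsFactors = FALSE)
  }
  strata <- data.frame(gene_id = sprintf("g%d", 1:400),
                       label = rep(c("base", "inflated"), each = 200))
  p <- vapply(1:5, function(s) {
    res <- mk(1000 + s)
    agg <- aggregate_wtct(res, strata, null_draws = 500, seed = s)
    agg$empirical_p[agg$label == "inflated"]
  }, numeric(1))
  expect_true(all(p < 0.05))
})

test_that("synthetic conditions with closer, stronger peaks rank higher", {
  # peaks of condition A placed tighter around TSSs and with twice the
  # significance scale must out-score condition B
  wins <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = 5000 + s, n_genes = 120, n_peaks = 400,
                      chrom_length = 6e6,
                      conditions = list(A = list(sig_scale = 2,
                                                 near_spread = 2e4),
                                        B = list(sig_scale = 1,
                                                 near_spread = 1e5)))
    gp <- simulate_genome_and_peaks(cfg)
    deg <- simulate_deg_table(cfg, gp$responsive,
                              S4Vectors::mcols(gp$genes)$gene_id)
    degs <- filter_deg(deg, logpv_min = Inf, absfc_min = log2(1.3),
                       use_padj = TRUE, padj_max = 0.1)
    tot <- vapply(c("A", "B"), function(cond) {
      links <- annotate_peaks(gp$peaks[[cond]], gp$genes)
      sum(wtct_scores(links, gp$peaks[[cond]], degs)$weighted_score)
    }, numeric(1))
    tot["A"] > tot["B"]
  }, logical(1))
  expect_true(all(wins))
})
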