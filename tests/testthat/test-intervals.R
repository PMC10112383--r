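test_that("pairwise overlap uses half-open, min-1-bp semantics", {
  a <- peak_ranges("chr1", 100, 200, "a")
  expect_true(spans_overlap(a, peak_ranges("chr1", 199, 300, "b")))
  expect_false(spans_overlap(a, peak_ranges("chr1", 200, 300, "b")))
  expect_false(spans_overlap(a, peak_ranges("chr2", 100, 200, "b")))
  # symmetry on random pairs
  set.seed(11)
  x <- df_to_peaks(random_regions_df(40, prefix = "x"))
  y <- df_to_peaks(random_regions_df(40, prefix = "y"))
  expect_identical(spans_overlap(x, y), spans_overlap(y, x))
})

test_that("set intersection labels identical and disjoint sets correctly", {
  s1 <- peak_ranges("chr1", 0, 10, "p1")
  s2 <- peak_ranges("chr1", 0, 10, "q1")
  res <- intersect_peak_sets(list(A = s1, B = s2))
  expect_true(all(res$membership$compartment == "A&B"))
  expect_equal(res$counts$n, c(1L, 1L))
  res2 <- intersect_peak_sets(list(A = peak_ranges("chr1", 0, 10, "p1"),
                                   B = peak_ranges("chr1", 20, 30, "q1")))
  expect_setequal(res2$membership$compartment, c("A", "B"))
  # empty set: zero counts, no error
  res3 <- intersect_peak_sets(list(A = s1, B = s1[0]))
  expect_equal(sum(res3$counts$n[res3$counts$set == "B"]), 0)
})

test_that("set intersection matches a brute-force all-pairs scan", {
  set.seed(42)
  dfs <- list(A = random_regions_df(50, prefix = "a"),
              B = random_regions_df(50, prefix = "b"),
              C = random_regions_df(50, prefix = "c"))
  res <- intersect_peak_sets(lapply(dfs, df_to_peaks))
  oracle <- venn_oracle(dfs)
  got <- res$membership[order(res$membership$set, res$membership$id), ]
  want <- oracle[order(oracle$set, oracle$id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # compartment counts sum to regions per set
  tot <- tapply(res$counts$n, res$counts$set, sum)
  expect_true(all(tot == 50))
})

test_that("annotation links peaks within the gene body and at the window edge", {
  genes <- toy_genes()
  links <- annotate_peaks(peak_ranges("chr1", 5000, 5200, "p"), genes)
  # links to gA (body overlap) and to gB (gap 44,800 < 100 kb), not gC
  expect_setequal(links$gene_id, c("gA", "gB"))
  inside <- links[links$gene_id == "gA", ]
  expect_equal(inside$zone, "within")
  expect_lt(abs(inside$distance), 10000)
  expect_equal(links$zone[links$gene_id == "gB"], "distal")
  # gene gA ends at 10,000: gap 100,000 links, 100,001 does not
  at <- annotate_peaks(peak_ranges("chr1", 110000, 110100, "p"),
                       gene_ranges("chr1", 1000, 10000, "gA", "+"))
  expect_equal(at$gene_id, "gA")
  beyond <- annotate_peaks(peak_ranges("chr1", 110001, 110101, "p"),
                           gene_ranges("chr1", 1000, 10000, "gA", "+"))
  expect_equal(nrow(beyond), 0)
  # no genes on the peak's chromosome: no links, no error
  none <- annotate_peaks(peak_ranges("chr9", 0, 100, "p"), genes)
  expect_equal(nrow(none), 0)
})

test_that("distance is signed midpoint-to-TSS on the gene strand", {
  gplus <- gene_ranges("chr1", 10000, 20000, "g+", "+")
  gminus <- gene_ranges("chr1", 10000, 20000, "g-", "-")
  up <- peak_ranges("chr1", 4950, 5050, "p")   # midpoint 5,000
  expect_equal(annotate_peaks(up, gplus)$distance, 5000 - 10000)
  expect_equal(annotate_peaks(up, gminus)$distance, 19999 - 5000)
})

test_that("annotation equals the exhaustive pair-scan oracle at 200 x 50", {
  set.seed(7)
  pk <- random_regions_df(200, n_chroms = 2, chrom_len = 4e5, prefix = "p")
  gn <- random_regions_df(50, n_chroms = 2, chrom_len = 4e5,
                          len_range = c(2000, 20000), prefix = "g")
  names(gn)[4] <- "gene_id"
  gn$strand <- sample(c("+", "-"), 50, replace = TRUE)
  peaks <- peak_ranges(pk$chrom, pk$start, pk$end, pk$id)
  genes <- gene_ranges(gn$chrom, gn$start, gn$end, gn$gene_id, gn$strand)
  got <- annotate_peaks(peaks, genes)
  got <- got[order(got$peak_id, got$gene_id), c("peak_id", "gene_id",
                                                "distance", "zone")]
  want <- annotate_oracle(pk, gn)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # referential integrity
  expect_true(all(got$peak_id %in% pk$id))
  expect_true(all(got$gene_id %in% gn$gene_id))
})

test_that("window is monotone and window=0 keeps exactly the body overlaps", {
  set.seed(13)
  pk <- random_regions_df(150, n_chroms = 2, chrom_len = 3e5, prefix = "p")
  gn <- random_regions_df(30, n_chroms = 2, chrom_len = 3e5,
                          len_range = c(2000, 20000), prefix = "g")
  peaks <- peak_ranges(pk$chrom, pk$start, pk$end, pk$id)
  genes <- gene_ranges(gn$chrom, gn$start, gn$end, gn$id,
                       sample(c("+", "-"), 30, replace = TRUE))
  key <- function(l) paste(l$peak_id, l$gene_id)
  l1 <- annotate_peaks(peaks, genes, window = 20000)
  l2 <- annotate_peaks(peaks, genes, window = 40000)
  expect_true(all(key(l1) %in% key(l2)))
  l0 <- annotate_peaks(peaks, genes, window = 0)
  expect_true(all(l0$zone == "within"))
  lw <- annotate_peaks(peaks, genes, window = 100000)
  expect_setequal(key(l0), key(lw[lw$zone == "within", ]))
})

test_that("nearest-only annotation keeps one closest gene per peak", {
  genes <- gene_ranges("chr1", c(1000, 30000), c(10000, 40000),
                       c("near", "far"), c("+", "+"))
  peak <- peak_ranges("chr1", 12000, 12100, "p")  # gaps 2,000 and 17,900
  all_links <- annotate_peaks(peak, genes)
  expect_equal(nrow(all_links), 2)
  near <- annotate_peaks(peak, genes, nearest_only = TRUE)
  expect_equal(near$gene_id, "near")
})

test_that("distance binning is half-open with signed 10-kb bins", {
  lk <- data.frame(distance = c(5000, -15000, -5000))
  b <- bin_link_distances(lk[1, , drop = FALSE])
  expect_equal(b$bin_start, 0); expect_equal(b$count, 1)
  b2 <- bin_link_distances(lk[2:3, , drop = FALSE])
  expect_equal(b2$bin_start, c(-20000, -10000))
  expect_equal(b2$count, c(1L, 1L))
  # boundary: distance exactly on a bin edge goes to the upper bin
  b3 <- bin_link_distances(data.frame(distance = 10000))
  expect_equal(b3$bin_start, 10000)
  expect_equal(nrow(bin_link_distances(lk[0, , drop = FALSE])), 0)
})

test_that("binning of 1,000 simulated links equals a direct tally", {
  set.seed(3)
  d <- round(runif(1000, -1e5, 1e5))
  b <- bin_link_distances(data.frame(distance = d), bin_width = 10000)
  expect_equal(sum(b$count), 1000)
  tally <- table(floor(d / 10000))
  got <- b$count[b$count > 0]
  expect_equal(got, as.integer(tally))
  expect_equal(b$bin_start[b$count > 0] / 10000,
               as.numeric(names(tally)))
})

test_that("state assignment picks maximal-overlap state with fixed tie order", {
  st <- state_ranges("chr1", c(0, 100), c(100, 300),
                     c("Promoter", "Enhancer"))
  inside <- assign_chrom_states(peak_ranges("chr1", 10, 60, "p"), st)
  expect_equal(inside$state, "Promoter")
  # 30 bp Promoter, 70 bp Enhancer
  split2 <- assign_chrom_states(peak_ranges("chr1", 70, 170, "p"), st)
  expect_equal(split2$state, "Enhancer")
  # exact tie: 50/50 -> first state in the declared order
  tie <- assign_chrom_states(peak_ranges("chr1", 50, 150, "p"), st,
                             state_order = c("Enhancer", "Promoter"))
  expect_equal(tie$state, "Enhancer")
  # no overlap -> unlabeled
  off <- assign_chrom_states(peak_ranges("chr2", 0, 50, "p"), st)
  expect_true(is.na(off$state))
})

test_that("state assignment equals a per-base counting oracle", {
  set.seed(21)
  # random tiling of two small chromosomes
  states <- c("Promoter", "Enhancer", "Transcribed", "Polycomb")
  st <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch) {
    edges <- sort(sample(200:4800, 15))
    data.frame(chrom = ch, start = c(0, edges), end = c(edges, 5000),
               state = sample(states, 16, replace = TRUE))
  }))
  pk <- random_regions_df(60, n_chroms = 2, chrom_len = 5000,
                          len_range = c(10, 800), prefix = "p")
  got <- assign_chrom_states(df_to_peaks(pk),
                             state_ranges(st$chrom, st$start, st$end, st$state),
                             state_order = states)
  expect_equal(got$state, state_oracle(pk, st, states))
})
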