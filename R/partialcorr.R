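#' First-order Pearson partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' single control variable `z`:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' identical (to numerical precision) to correlating the residuals of
#' `x ~ z` and `y ~ z`.
#'
#' @param x,y,z numeric vectors of equal length, n >= 4, each with
#'   positive variance.
#' @return the partial correlation coefficient.
#' @export
partial_corr <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stopf("x, y, z must have equal length")
  if (n < 4) stopf("partial correlation needs at least 4 samples")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0) {
    stopf("all inputs must have positive variance")
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stopf("partial correlation undefined: control variable is collinear with x or y")
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Coregulator screen by change in TF-target correlation (delta.corr)
#'
#' For each candidate coregulator c, computes the mean Pearson
#' correlation between the TF and its target genes, the mean first-order
#' partial correlation controlling for c, and their difference
#' `delta_corr = mean(r) - mean(r_partial)`. Positive values indicate
#' that c accounts for part of the apparent TF-target coupling.
#' Significance is a two-sided empirical p from permuting c's sample
#' vector, which breaks its relation to both TF and targets while
#' preserving its marginal distribution.
#'
#' @param expr numeric matrix, samples x genes, with gene column names.
#' @param tf gene id of the transcription factor.
#' @param targets character vector of target gene ids (must not contain
#'   `tf`).
#' @param coregulators character vector of candidate coregulator ids.
#' @param permutations number of permutations (default 1000).
#' @param seed RNG seed (required).
#' @param per_target return the per-target delta matrix as an attribute.
#' @return data.frame: coregulator, n_targets, mean_r, mean_r_partial,
#'   delta_corr, empirical_p.
#' @export
delta_corr_screen <- function(expr, tf, targets, coregulators,
                              permutations = 1000, seed,
                              per_target = FALSE) {
  if (missing(seed)) stopf("seed is required for the permutation test")
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  n <- nrow(expr)
  if (n < 4) stopf("need at least 4 samples")
  ids <- c(tf, targets, coregulators)
  miss <- setdiff(ids, colnames(expr))
  if (length(miss)) stopf("genes absent from the matrix: %s",
                          paste(miss, collapse = ", "))
  if (tf %in% targets) stopf("the TF cannot be its own target")
  x <- expr[, tf]
  Y <- expr[, targets, drop = FALSE]
  r_ty <- as.numeric(stats::cor(x, Y))
  mean_r <- mean(r_ty)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  res <- lapply(coregulators, function(cg) {
    z <- expr[, cg]
    obs <- pcor_means(x, Y, z, r_ty)
    # permutations of z: one n x B matrix, all correlations vectorised
    P <- vapply(seq_len(permutations), function(b) z[sample.int(n)],
                numeric(n))
    r_tz <- as.numeric(stats::cor(x, P))
    r_yz <- stats::cor(Y, P)                       # T x B
    num <- sweep(-(outer(rep(1, length(r_ty)), r_tz) * r_yz), 1, r_ty, "+")
    den <- sqrt(outer(rep(1, length(r_ty)), 1 - r_tz^2) * (1 - r_yz^2))
    null_delta <- mean_r - colMeans(num / den)
    p <- (1 + sum(abs(null_delta) >= abs(obs$delta), na.rm = TRUE)) /
      (permutations + 1)
    data.frame(coregulator = cg, n_targets = length(targets),
               mean_r = mean_r, mean_r_partial = obs$mean_partial,
               delta_corr = obs$delta, empirical_p = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (per_target) {
    pt <- vapply(coregulators, function(cg) {
      r_ty - pcor_vec(x, Y, expr[, cg], r_ty)
    }, numeric(length(targets)))
    attr(out, "per_target_delta") <-
      matrix(pt, nrow = length(targets),
             dimnames = list(targets, coregulators))
  }
  out
}

pcor_vec <- function(x, Y, z, r_ty) {
  r_tz <- stats::cor(x, z)
  r_yz <- as.numeric(stats::cor(Y, z))
  if (abs(r_tz) >= 1 - 1e-12 || any(abs(r_yz) >= 1 - 1e-12)) {
    stopf("partial correlation undefined: coregulator collinear with TF or a target")
  }
  (r_ty - r_tz * r_yz) / sqrt((1 - r_tz^2) * (1 - r_yz^2))
}

pcor_means <- function(x, Y, z, r_ty) {
  pc <- pcor_vec(x, Y, z, r_ty)
  list(mean_partial = mean(pc), delta = mean(r_ty) - mean(pc))
}

#' Contrast a coregulator screen between two sample groups
#'
#' Joins two [delta_corr_screen()] results by coregulator and flags
#' coregulators whose effect is significant in exactly one group at
#' level `alpha` ("group-specific"). Coregulators present in only one
#' result are kept with the other side `NA`.
#'
#' @param results_a,results_b data.frames from [delta_corr_screen()].
#' @param labels length-2 character naming the groups.
#' @param alpha significance level for the group-specific flag.
#' @return data.frame with per-group delta_corr and empirical_p columns
#'   plus `specific_to` (one of the labels or `NA`).
#' @export
group_contrast <- function(results_a, results_b, labels = c("A", "B"),
                           alpha = 0.05) {
  keep <- c("coregulator", "delta_corr", "empirical_p")
  a <- results_a[keep]; b <- results_b[keep]
  names(a)[2:3] <- paste0(c("delta_corr_", "empirical_p_"), labels[1])
  names(b)[2:3] <- paste0(c("delta_corr_", "empirical_p_"), labels[2])
  m <- merge(a, b, by = "coregulator", all = TRUE, sort = TRUE)
  pa <- m[[paste0("empirical_p_", labels[1])]]
  pb <- m[[paste0("empirical_p_", labels[2])]]
  sig_a <- !is.na(pa) & pa < alpha
  sig_b <- !is.na(pb) & pb < alpha
  m$specific_to <- ifelse(sig_a & !sig_b, labels[1],
                          ifelse(sig_b & !sig_a, labels[2], NA_character_))
  m
}

#' Balance two sample groups by seeded subsampling
#'
#' Returns sample indices giving equal group sizes, subsampling the
#' larger group without replacement (mirrors analyses run on equal
#' numbers of tumors per ancestry group).
#'
#' @param group factor/character of per-sample group labels (2 levels).
#' @param seed RNG seed (required).
#' @return integer vector of retained sample indices, sorted.
#' @export
balance_groups <- function(group, seed) {
  if (missing(seed)) stopf("seed is required for subsampling")
  tab <- table(group)
  if (length(tab) != 2) stopf("exactly two groups are required")
  n <- min(tab)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- unlist(lapply(names(tab), function(g) {
    w <- which(group == g)
    if (length(w) > n) sort(sample(w, n)) else w
  }))
  sort(idx)
}
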