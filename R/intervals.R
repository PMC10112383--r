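#' Genomic containers used throughout the package
#'
#' All intervals enter the package in BED convention (0-based start,
#' half-open end) and are stored internally as `GRanges` (1-based, closed).
#' The constructors below validate the field contracts once at the boundary
#' so downstream code can assume them.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param id unique region identifiers (peaks) or `gene_id` (genes).
#' @param significance optional non-negative `-log10` adjusted p per region.
#' @param direction optional sign of change per region (+1 gain, -1 loss, 0).
#' @return A `GRanges` with the type-specific metadata columns.
#' @name containers
NULL

#' @rdname containers
#' @export
peak_ranges <- function(chrom, start, end, id = NULL,
                        significance = NULL, direction = NULL) {
  n <- length(chrom)
  if (is.null(id)) id <- sprintf("peak_%d", seq_len(n))
  check_coords(start, end)
  if (anyDuplicated(id)) stopf("peak ids must be unique within a peak set")
  if (!is.null(significance) && any(significance < 0, na.rm = TRUE)) {
    stopf("peak significance must be >= 0 (it is a -log10 p-value)")
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end),
    id = as.character(id),
    significance = if (is.null(significance)) NA_real_ else as.numeric(significance),
    direction = if (is.null(direction)) 0L else as.integer(direction)
  )
  gr
}

#' @rdname containers
#' @param gene_id unique gene identifiers.
#' @param strand gene strand, `+` or `-`.
#' @export
gene_ranges <- function(chrom, start, end, gene_id, strand) {
  check_coords(start, end)
  if (anyDuplicated(gene_id)) stopf("gene_id must be unique within a gene set")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end), strand = strand,
    gene_id = as.character(gene_id),
    tss = ifelse(strand == "+", as.numeric(start), as.numeric(end) - 1)
  )
  gr
}

#' @rdname containers
#' @param state chromatin-state labels (e.g. Promoter, Enhancer, Polycomb).
#' @export
state_ranges <- function(chrom, start, end, state) {
  check_coords(start, end)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               state = as.character(state))
  sp <- split(gr, GenomeInfoDb::seqnames(gr))
  bad <- vapply(sp, function(g) {
    length(g) > 1 && !IRanges::isDisjoint(g)
  }, logical(1))
  if (any(bad)) stopf("chromatin-state segments overlap on: %s",
                      paste(names(sp)[bad], collapse = ", "))
  gr
}

# Querying sets on disjoint chromosomes is a legitimate no-hit case, not
# something the caller should be warned about.
quiet_overlap <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

check_coords <- function(start, end) {
  if (any(start < 0) || any(start >= end)) {
    stopf("coordinates must satisfy 0 <= start < end (0-based half-open)")
  }
  invisible(NULL)
}

# 0-based midpoint of a GRanges (BED convention: floor((start0+end0)/2)).
midpoint0 <- function(gr) {
  floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
}

#' Pairwise interval overlap (minimum 1 bp)
#'
#' Vectorised over pairs: element i of `a` is compared with element i of
#' `b`. Half-open semantics — intervals that merely touch do not overlap.
#' Different chromosomes give `FALSE`, never an error.
#'
#' @param a,b `GRanges` of equal length (recycled if one has length 1).
#' @return logical vector.
#' @export
spans_overlap <- function(a, b) {
  if (length(a) == 1) a <- rep(a, length(b))
  if (length(b) == 1) b <- rep(b, length(a))
  if (length(a) != length(b)) stopf("a and b must have equal length")
  same <- as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b))
  inter <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1
  same & inter >= 1
}

#' Multi-set overlap membership (Venn compartments)
#'
#' Labels every region with the subset of peak sets it overlaps by at
#' least 1 bp (always including its own set) and tallies regions per
#' compartment within each set. Compartment counts therefore sum to the
#' number of regions in that set.
#'
#' @param sets named list (>= 2) of peak `GRanges`.
#' @return list with `membership` (set, id, compartment) and `counts`
#'   (set, compartment, n) data.frames.
#' @export
intersect_peak_sets <- function(sets) {
  if (length(sets) < 2) stopf("need at least two peak sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("peak sets must be uniquely named")
  }
  labs <- names(sets)
  membership <- lapply(labs, function(li) {
    g <- sets[[li]]
    if (length(g) == 0) {
      return(data.frame(set = character(), id = character(),
                        compartment = character()))
    }
    hit <- vapply(labs, function(lj) {
      if (lj == li) return(rep(TRUE, length(g)))
      if (length(sets[[lj]]) == 0) return(rep(FALSE, length(g)))
      quiet_overlap(IRanges::overlapsAny(g, sets[[lj]], minoverlap = 1L))
    }, logical(length(g)))
    hit <- matrix(hit, nrow = length(g), dimnames = list(NULL, labs))
    comp <- apply(hit, 1, function(r) paste(labs[r], collapse = "&"))
    data.frame(set = li, id = S4Vectors::mcols(g)$id, compartment = comp)
  })
  membership <- do.call(rbind, membership)
  counts <- as.data.frame(table(set = membership$set,
                                compartment = membership$compartment),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  counts <- counts[counts$n > 0, , drop = FALSE]
  counts <- counts[order(counts$set, counts$compartment), ]
  rownames(counts) <- NULL
  list(membership = membership, counts = counts)
}

#' Annotate peaks to genes within a window
#'
#' A peak links to a gene if it overlaps the gene body by >= 1 bp
#' (`zone = "within"`) or the gap between the peak and the gene span is
#' at most `window` bp. With `window = 0` only body-overlap links are
#' returned. The reported `distance` is the signed bp from peak midpoint
#' to the gene TSS, negative upstream of the TSS on the gene strand;
#' linkage itself is strand-agnostic. Peaks without body overlap are
#' zoned `"proximal"` when `|distance| <= proximal_cutoff`, else
#' `"distal"`.
#'
#' @param peaks peak `GRanges` (see [peak_ranges()]).
#' @param genes gene `GRanges` (see [gene_ranges()]).
#' @param window maximum peak-to-gene-span gap in bp (default 100000).
#' @param proximal_cutoff promoter-proximal midpoint-to-TSS cutoff in bp.
#' @param nearest_only if `TRUE`, keep only each peak's nearest gene
#'   (smallest gap, ties by `|distance|`, then gene id).
#' @return data.frame with columns peak_id, gene_id, chrom, distance,
#'   zone, state (`NA`; fill with [assign_chrom_states()]).
#' @export
annotate_peaks <- function(peaks, genes, window = 100000L,
                           proximal_cutoff = 10000L, nearest_only = FALSE) {
  if (window < 0) stopf("window must be >= 0")
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      chrom = character(), distance = integer(),
                      zone = character(), state = character())
  if (length(peaks) == 0 || length(genes) == 0) return(empty)
  maxgap <- if (window == 0) -1L else as.integer(window)
  hits <- quiet_overlap(
    GenomicRanges::findOverlaps(peaks, genes, maxgap = maxgap,
                                ignore.strand = TRUE))
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  p <- peaks[qh]
  g <- genes[sh]
  body <- spans_overlap(p, g)
  mid <- midpoint0(p)
  tss <- S4Vectors::mcols(g)$tss
  dist <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                 tss - mid, mid - tss)
  zone <- ifelse(body, "within",
                 ifelse(abs(dist) <= proximal_cutoff, "proximal", "distal"))
  links <- data.frame(
    peak_id = S4Vectors::mcols(p)$id,
    gene_id = S4Vectors::mcols(g)$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(p)),
    distance = as.integer(dist),
    zone = zone,
    state = NA_character_
  )
  if (nearest_only && nrow(links) > 0) {
    gap <- GenomicRanges::distance(p, g, ignore.strand = TRUE)
    ord <- order(links$peak_id, gap, abs(links$distance), links$gene_id)
    links <- links[ord, , drop = FALSE]
    links <- links[!duplicated(links$peak_id), , drop = FALSE]
  }
  rownames(links) <- NULL
  links
}

#' Histogram of peak:gene link distances
#'
#' Counts links in half-open signed distance bins `[k*w, (k+1)*w)`.
#' When `range` is given the histogram covers it completely (zero bins
#' included); otherwise only the observed span.
#'
#' @param links link data.frame from [annotate_peaks()].
#' @param bin_width bin width in bp (default 10000).
#' @param range optional length-2 numeric; distances outside are dropped.
#' @return data.frame with bin_start, bin_end, count.
#' @export
bin_link_distances <- function(links, bin_width = 10000L, range = NULL) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  d <- links$distance
  if (!is.null(range)) {
    lo <- floor(range[1] / bin_width)
    hi <- ceiling(range[2] / bin_width) - 1
    d <- d[d >= lo * bin_width & d < (hi + 1) * bin_width]
  } else if (length(d) == 0) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  } else {
    lo <- min(floor(d / bin_width))
    hi <- max(floor(d / bin_width))
  }
  k <- lo:hi
  cnt <- tabulate(floor(d / bin_width) - lo + 1, nbins = length(k))
  data.frame(bin_start = k * bin_width, bin_end = (k + 1) * bin_width,
             count = cnt)
}

#' Assign each peak its dominant chromatin state
#'
#' Each peak takes the state with which it shares the most base pairs;
#' peaks overlapping no segment stay `NA`. Ties go to the state that
#' comes first in `state_order` (default: order of first appearance in
#' `states`), making the assignment deterministic.
#'
#' @param peaks peak `GRanges`.
#' @param states state `GRanges` (see [state_ranges()]).
#' @param state_order character vector fixing the tie-break priority.
#' @return data.frame with peak_id and state.
#' @export
assign_chrom_states <- function(peaks, states, state_order = NULL) {
  if (is.null(state_order)) state_order <- unique(S4Vectors::mcols(states)$state)
  out <- data.frame(peak_id = S4Vectors::mcols(peaks)$id,
                    state = NA_character_)
  if (length(peaks) == 0 || length(states) == 0) return(out)
  hits <- quiet_overlap(
    GenomicRanges::findOverlaps(peaks, states, minoverlap = 1L,
                                ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(peaks[qh]), GenomicRanges::ranges(states[sh])))
  st <- S4Vectors::mcols(states)$state[sh]
  bp <- stats::aggregate(ov, list(peak = qh, state = st), sum)
  pri <- match(bp$state, state_order)
  pri[is.na(pri)] <- length(state_order) + 1L
  ord <- order(bp$peak, -bp$x, pri)
  bp <- bp[ord, , drop = FALSE]
  best <- bp[!duplicated(bp$peak), , drop = FALSE]
  out$state[best$peak] <- best$state
  out
}

#' Attach chromatin states to a link table
#'
#' @param links data.frame from [annotate_peaks()].
#' @param state_map data.frame from [assign_chrom_states()].
#' @return `links` with the state column filled by peak id.
#' @export
add_link_states <- function(links, state_map) {
  links$state <- state_map$state[match(links$peak_id, state_map$peak_id)]
  links
}
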