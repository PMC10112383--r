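#' Readers and writers for the standard input formats
#'
#' Peaks and chromatin-state segmentations travel as BED (score column =
#' `-log10` adjusted p for peaks, name column = state label for
#' segmentations; peak direction is encoded on the strand field). Gene
#' models travel as GFF3 (`type == "gene"`) or BED6/BED12. Tabular data
#' (DEG/miRNA tables, NES tables, expression matrices) travel as TSV.
#' All coordinate conversion between BED's 0-based half-open convention
#' and the 1-based `GRanges` representation happens here, via
#' `rtracklayer`.
#'
#' @param path file path.
#' @return the corresponding container (`GRanges` or data.frame).
#' @name io
NULL

#' @rdname io
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mc <- S4Vectors::mcols(gr)
  id <- if (!is.null(mc$name)) mc$name else sprintf("peak_%d", seq_along(gr))
  if (anyDuplicated(id)) stopf("%s: duplicate peak ids in name column", path)
  sig <- if (!is.null(mc$score)) as.numeric(mc$score) else NA_real_
  if (any(sig < 0, na.rm = TRUE)) {
    stopf("%s: negative significance in score column", path)
  }
  dir <- c(`+` = 1L, `-` = -1L, `*` = 0L)[as.character(GenomicRanges::strand(gr))]
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                GenomicRanges::ranges(gr),
                                id = as.character(id), significance = sig,
                                direction = unname(dir))
  out
}

#' @rdname io
#' @param peaks peak `GRanges` from [peak_ranges()] or [read_peaks()].
#' @export
write_peaks <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  strand <- c("-", "*", "+")[mc$direction + 2L]
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                               GenomicRanges::ranges(peaks), strand = strand,
                               name = mc$id,
                               score = ifelse(is.na(mc$significance), 0,
                                              mc$significance))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname io
#' @export
read_genes <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  if (fmt == "GFF3") {
    if (!is.null(mc$type)) {
      keep <- as.character(mc$type) == "gene"
      gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
    }
    gene_id <- mc$gene_id %||% mc$ID %||% mc$Name
    if (is.null(gene_id)) stopf("%s: no gene_id/ID/Name attribute", path)
  } else {
    gene_id <- mc$name
    if (is.null(gene_id)) stopf("%s: BED gene model needs a name column", path)
  }
  if (anyDuplicated(gene_id)) stopf("%s: duplicate gene ids", path)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*")) stopf("%s: gene models must be stranded", path)
  tss <- ifelse(st == "+", GenomicRanges::start(gr) - 1,
                GenomicRanges::end(gr) - 1)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         GenomicRanges::ranges(gr), strand = st,
                         gene_id = as.character(gene_id), tss = as.numeric(tss))
}

#' @rdname io
#' @param genes gene `GRanges` from [gene_ranges()] or [read_genes()].
#' @export
write_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                               GenomicRanges::ranges(genes),
                               strand = GenomicRanges::strand(genes),
                               type = "gene",
                               ID = S4Vectors::mcols(genes)$gene_id)
  rtracklayer::export(gr, path, format = "GFF3")
  # rtracklayer stamps a ##date header; drop it so identical inputs
  # always produce identical bytes.
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' @rdname io
#' @export
read_states <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- S4Vectors::mcols(gr)$name
  if (is.null(st)) stopf("%s: state segmentation needs the state in the name column", path)
  state_ranges(as.character(GenomeInfoDb::seqnames(gr)),
               GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
               state = st)
}

#' @rdname io
#' @param states state `GRanges`.
#' @export
write_states <- function(states, path) {
  gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(states),
                               GenomicRanges::ranges(states),
                               name = S4Vectors::mcols(states)$state)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname io
#' @param what label used in error messages.
#' @param id_col name of the identifier column expected in the TSV.
#' @export
read_deg_table <- function(path, id_col = "gene_id", what = "DEG table") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!id_col %in% names(df) && "id" %in% names(df)) {
    names(df)[names(df) == "id"] <- id_col
  }
  assert_columns(df, c(id_col, "log2fc"), what)
  df
}

#' @rdname io
#' @export
read_nes_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  assert_columns(df, c("term", "nes_a", "nes_b"), "NES table")
  df
}

#' @rdname io
#' @param genes_in_columns `TRUE` when the TSV is samples x genes
#'   (default); `FALSE` transposes a genes x samples matrix on read.
#' @export
read_expression <- function(path, genes_in_columns = TRUE) {
  df <- utils::read.delim(path, comment.char = "#", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!genes_in_columns) m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' @rdname io
#' @param x data.frame to serialise.
#' @param provenance optional named list written as `# key: value`
#'   comment lines ahead of the header.
#' @export
write_tsv_report <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, "")), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!startsWith(x, "#")])
  x[nzchar(x)]
}
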