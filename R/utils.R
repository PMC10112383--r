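#' Round half away from zero
#'
#' Fixed-point rounding where exact .5 cases go up (for positive input),
#' matching how percentages are conventionally printed in report tables.
#' Base [round()] uses round-half-to-even, which would print 85.65 as 85.6.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded to `digits` places, half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Deterministic md5 of an R object via canonical YAML serialisation;
# used for report provenance so identical configs hash identically.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
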