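# Internal helpers shared across modules.

#' @import methods
#' @importFrom Matrix sparseMatrix readMM writeMM t rowSums colSums
#' @importFrom stats median quantile rnbinom rpois runif rnorm qnbinom pnorm cor rlnorm
#' @importFrom utils head packageVersion
NULL

# Intervals are 0-based half-open everywhere in this package (BED convention).
# GRanges is 1-based closed, so conversion happens only at the findOverlaps
# boundary, via this helper.
granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1L, end = end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# Named character vector barcode -> label.
validate_annotation <- function(annotation) {
  assert_that(is.character(annotation) && !is.null(names(annotation)),
              "annotation must be a named character vector (barcode -> label)")
  assert_that(!anyDuplicated(names(annotation)),
              "annotation contains duplicated barcodes")
  assert_that(all(nzchar(annotation)), "annotation labels must be non-empty")
  invisible(annotation)
}

validate_intervals <- function(df, what = "interval") {
  assert_that(all(c("chrom", "start", "end") %in% names(df)),
              paste0(what, " table must have chrom/start/end columns"))
  assert_that(all(nzchar(df$chrom)), paste0(what, ": empty chromosome name"))
  assert_that(all(df$start >= 0), paste0(what, ": negative start coordinate"))
  assert_that(all(df$start < df$end), paste0(what, ": start must be < end"))
  invisible(df)
}

as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# triplet (i, j, x) view of a dgCMatrix, non-zeros only
sparse_triplets <- function(m) {
  m <- as_dgc(m)
  list(i = m@i + 1L,
       j = rep(seq_len(ncol(m)), diff(m@p)),
       x = m@x)
}
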