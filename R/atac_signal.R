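# Fragments + regulatory annotation -> element-by-cell raw count matrix.

#' Pipeline configuration
#'
#' Holds the constants of the accessibility pipeline. Defaults: a -500/+200 bp
#' window around the TSS, strict MAPQ > 30 filtering, and +4/-5 bp Tn5
#' offsets (the Tn5 transposase binds as a dimer and inserts two adaptors
#' 9 bp apart, so the Watson-strand cut is shifted +4 and the Crick-strand
#' cut -5 to centre on the insertion).
#'
#' @param flank_up Upstream promoter flank in bp (default 500).
#' @param flank_down Downstream promoter flank in bp (default 200).
#' @param mapq_min Fragments with MAPQ strictly greater than this are kept
#'   when a MAPQ column is available (default 30).
#' @param tn5_plus_offset Offset added to fragment starts (default +4).
#' @param tn5_minus_offset Offset added to fragment ends (default -5).
#' @param sigmoid_k Steepness of the activity sigmoid; `NULL` (default)
#'   auto-calibrates to 4 / median positive (value - threshold) gap, so a
#'   typical open element maps to an activity of about 0.88.
#' @param gc_bins Number of equal-frequency GC bins (default 10).
#' @param lhs_strata Number of Latin-hypercube rank strata for dropout
#'   simulation (default 10).
#' @param count_mode `"overlap"` (a fragment counts in every window it
#'   overlaps by >= 1 bp, the default) or `"insertion"` (each Tn5 insertion
#'   end falling in a window counts).
#' @param seed Integer seed used by stochastic stages.
#' @return A list of class `epiimpute_config`.
#' @export
pipeline_config <- function(flank_up = 500L, flank_down = 200L, mapq_min = 30L,
                            tn5_plus_offset = 4L, tn5_minus_offset = -5L,
                            sigmoid_k = NULL, gc_bins = 10L, lhs_strata = 10L,
                            count_mode = c("overlap", "insertion"), seed = 1L) {
  count_mode <- match.arg(count_mode)
  assert_that(flank_up >= 0 && flank_down >= 0, "flanks must be >= 0")
  assert_that(is.null(sigmoid_k) || sigmoid_k > 0, "sigmoid_k must be > 0")
  structure(list(flank_up = as.integer(flank_up),
                 flank_down = as.integer(flank_down),
                 mapq_min = as.integer(mapq_min),
                 tn5_plus_offset = as.integer(tn5_plus_offset),
                 tn5_minus_offset = as.integer(tn5_minus_offset),
                 sigmoid_k = sigmoid_k, gc_bins = as.integer(gc_bins),
                 lhs_strata = as.integer(lhs_strata), count_mode = count_mode,
                 seed = as.integer(seed)),
            class = "epiimpute_config")
}

#' Apply Tn5 insertion offsets to fragments
#'
#' Shifts fragment starts by +4 bp (Watson-strand insertion) and ends by
#' -5 bp (Crick-strand insertion). Fragments whose interval becomes empty or
#' inverted are dropped with a warning. Fragments read with
#' `shifted = TRUE` (10x convention) are returned unchanged: the shift is
#' applied exactly once.
#'
#' @param frags Fragments data.frame from [read_fragments()].
#' @param config A [pipeline_config()].
#' @return Shifted fragments with attribute `shifted = TRUE`; attribute
#'   `n_dropped_shift` counts dropped records.
#' @export
tn5_shift <- function(frags, config = pipeline_config()) {
  if (isTRUE(attr(frags, "shifted"))) return(frags)
  start <- frags$start + config$tn5_plus_offset
  end <- frags$end + config$tn5_minus_offset
  bad <- start >= end | start < 0
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(n_bad, " fragment(s) dropped: empty interval after Tn5 shift",
            call. = FALSE)
    out <- frags[!bad, , drop = FALSE]
    out$start <- start[!bad]
    out$end <- end[!bad]
  } else {
    out <- frags
    out$start <- start
    out$end <- end
  }
  attr(out, "shifted") <- TRUE
  attr(out, "malformed") <- attr(frags, "malformed")
  attr(out, "n_dropped_shift") <- n_bad
  out
}

#' Promoter window around a TSS
#'
#' For a "+" gene the window is `[TSS - flank_up, TSS + flank_down)`; for a
#' "-" gene the strand-reflected window `[TSS - flank_down + 1,
#' TSS + flank_up + 1)`. Coordinates are clamped at 0. With the defaults the
#' window covers -500/+200 bp around the TSS in the direction of
#' transcription.
#'
#' @param tss Integer TSS position(s), 0-based.
#' @param strand `"+"` or `"-"` (vectorized). `"."` is an error: the window
#'   is strand-dependent.
#' @param config A [pipeline_config()].
#' @return data.frame with `start` and `end` columns (0-based half-open).
#' @export
promoter_window <- function(tss, strand, config = pipeline_config()) {
  assert_that(all(strand %in% c("+", "-")),
              "promoter window requires strand '+' or '-'")
  plus <- strand == "+"
  start <- ifelse(plus, tss - config$flank_up, tss - config$flank_down + 1L)
  end <- ifelse(plus, tss + config$flank_down, tss + config$flank_up + 1L)
  start <- pmax(start, 0L)
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Materialize counting windows for regulatory elements
#'
#' Promoters get the strand-aware -500/+200 bp TSS window (the TSS of a "+"
#' record is its `start`, of a "-" record its `end - 1`). Enhancers have no
#' strand: intervals shorter than `flank_up + flank_down` bp are replaced by
#' a window of that size around their midpoint; longer intervals are used
#' as-is.
#'
#' @param elements A `regulatory_elements` data.frame.
#' @param config A [pipeline_config()].
#' @return The elements with `start`/`end` replaced by window coordinates.
#' @export
element_windows <- function(elements, config = pipeline_config()) {
  out <- elements
  win_len <- config$flank_up + config$flank_down
  prom <- elements$kind == "promoter"
  if (any(prom)) {
    tss <- ifelse(elements$strand[prom] == "+",
                  elements$start[prom], elements$end[prom] - 1L)
    w <- promoter_window(tss, elements$strand[prom], config)
    out$start[prom] <- w$start
    out$end[prom] <- w$end
  }
  enh <- !prom
  if (any(enh)) {
    short <- enh & (elements$end - elements$start) < win_len
    if (any(short)) {
      mid <- (elements$start[short] + elements$end[short]) %/% 2L
      out$start[short] <- pmax(mid - config$flank_up, 0L)
      out$end[short] <- mid + config$flank_down
    }
  }
  out
}

filter_mapq <- function(frags, config) {
  if (is.null(frags$mapq)) return(frags)
  keep <- frags$mapq > config$mapq_min
  if (all(keep)) frags else frags[keep, , drop = FALSE]
}

#' Count fragments per regulatory-element window per cell
#'
#' A Tn5-shifted fragment contributes 1 to element `e` for its barcode's cell
#' iff it overlaps `e`'s window by at least 1 bp (`count_mode = "overlap"`,
#' the default) or one of its insertion ends falls inside the window
#' (`"insertion"`). Fragments overlapping k windows count in all k. When a
#' `mapq` column is present only fragments with MAPQ strictly greater than
#' `config$mapq_min` are kept. Barcodes absent from `cells` are dropped and
#' tallied in the `"n_unmatched_barcodes"` attribute.
#'
#' @param frags Tn5-shifted fragments (see [tn5_shift()]).
#' @param elements Regulatory elements with materialized windows
#'   (see [element_windows()]).
#' @param cells Character vector of annotated ATAC barcodes defining the
#'   matrix columns.
#' @param config A [pipeline_config()].
#' @return Sparse elements-by-cells integer count matrix (dgCMatrix).
#' @export
count_fragments <- function(frags, elements, cells, config = pipeline_config()) {
  assert_that(nrow(elements) > 0, "no regulatory elements to count over")
  assert_that(length(cells) > 0 && !anyDuplicated(cells),
              "cells must be a non-empty set of unique barcodes")
  frags <- filter_mapq(frags, config)
  keep <- frags$barcode %in% cells
  n_unmatched <- sum(!keep)
  if (n_unmatched > 0) frags <- frags[keep, , drop = FALSE]
  assert_that(nrow(frags) > 0,
              paste0("no fragments retained after MAPQ/barcode filtering (",
                     n_unmatched, " barcode-unmatched)"))
  win <- granges0(elements$chrom, elements$start, elements$end)
  cell_idx <- match(frags$barcode, cells)

  if (config$count_mode == "overlap") {
    fr <- granges0(frags$chrom, frags$start, frags$end)
    hits <- GenomicRanges::findOverlaps(fr, win, minoverlap = 1L)
    i <- S4Vectors::subjectHits(hits)
    j <- cell_idx[S4Vectors::queryHits(hits)]
  } else {
    # each shifted insertion end is a 1 bp event
    pos <- c(frags$start, frags$end - 1L)
    fr <- granges0(rep(frags$chrom, 2L), pos, pos + 1L)
    hits <- GenomicRanges::findOverlaps(fr, win, minoverlap = 1L)
    i <- S4Vectors::subjectHits(hits)
    j <- cell_idx[((S4Vectors::queryHits(hits) - 1L) %% nrow(frags)) + 1L]
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(nrow(elements), length(cells)),
                            dimnames = list(elements$id, cells))
  attr(m, "n_unmatched_barcodes") <- n_unmatched
  m
}

#' Per-cell blacklist coverage rate
#'
#' For each cell, the number of Tn5-shifted, MAPQ-passing fragments
#' overlapping any blacklist region divided by the total blacklist length in
#' bp. Blacklist regions (ENCODE-style centromeric/telomeric artefact
#' regions) carry no true regulatory signal, so this rate estimates the
#' per-cell background noise level per bp.
#'
#' @param frags Tn5-shifted fragments.
#' @param blacklist data.frame of blacklist intervals (`chrom`,`start`,`end`).
#' @param cells Character vector of annotated ATAC barcodes.
#' @param config A [pipeline_config()].
#' @return Named numeric vector, one fragments-per-bp rate per cell.
#' @export
blacklist_coverage <- function(frags, blacklist, cells,
                               config = pipeline_config()) {
  validate_intervals(blacklist, "blacklist region")
  total_len <- sum(blacklist$end - blacklist$start)
  assert_that(total_len > 0, "blacklist has zero total length")
  frags <- filter_mapq(frags, config)
  keep <- frags$barcode %in% cells
  if (!all(keep)) frags <- frags[keep, , drop = FALSE]
  counts <- stats::setNames(numeric(length(cells)), cells)
  if (nrow(frags) > 0) {
    fr <- granges0(frags$chrom, frags$start, frags$end)
    bl <- granges0(blacklist$chrom, blacklist$start, blacklist$end)
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(fr, bl)))
    if (length(hit)) {
      tab <- table(frags$barcode[hit])
      counts[names(tab)] <- as.numeric(tab)
    }
  }
  counts / total_len
}
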