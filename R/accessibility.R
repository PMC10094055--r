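# Normalized element accessibility -> per-gene activity probabilities.

#' Build the per-cell threshold accessibility vector
#'
#' The expected background (noise) count in one counting window, per cell:
#' the blacklist-region fragment rate per bp times the window length
#' (`flank_up + flank_down`, 700 bp by default). Element coverage above this
#' value is what the pipeline calls "open". To put threshold and signal on
#' one scale, the pipeline carries the raw threshold through the same
#' normalization transforms as the element matrix, by appending it as a
#' pseudo-element row (see [normalize_with_threshold()]).
#'
#' @param blacklist_per_bp Named numeric vector from [blacklist_coverage()].
#' @param config A [pipeline_config()].
#' @return Named numeric vector of raw per-cell thresholds (>= 0).
#' @export
build_threshold_vector <- function(blacklist_per_bp, config = pipeline_config()) {
  theta <- blacklist_per_bp * (config$flank_up + config$flank_down)
  assert_that(all(theta >= 0), "threshold vector must be non-negative")
  theta
}

THRESHOLD_ID <- "__threshold__"

#' Normalize an element count matrix together with its threshold vector
#'
#' Appends the raw threshold vector as a pseudo-element row, applies
#' [smooth_quantile_normalize()] then [gc_normalize()] (the pseudo-element
#' has no GC fraction and passes through the GC step unscaled), and splits
#' the result back into normalized element values and a normalized threshold.
#'
#' @param counts Elements-by-cells count matrix (rows named by element id).
#' @param theta Raw threshold vector from [build_threshold_vector()].
#' @param groups Named character vector: ATAC cell -> cell-type label.
#' @param gc_fraction GC fraction per element (NA allowed).
#' @param config A [pipeline_config()].
#' @return List with `values` (normalized element matrix) and `theta`
#'   (normalized threshold per cell).
#' @export
normalize_with_threshold <- function(counts, theta, groups, gc_fraction,
                                     config = pipeline_config()) {
  X <- as.matrix(counts)
  assert_that(all(colnames(X) %in% names(theta)),
              "threshold vector missing cells present in the count matrix")
  aug <- rbind(X, matrix(theta[colnames(X)], nrow = 1,
                         dimnames = list(THRESHOLD_ID, colnames(X))))
  norm <- smooth_quantile_normalize(aug, groups)
  gc_aug <- c(gc_fraction, NA_real_)
  # the pseudo-row's NA GC is by design: only warn about real elements
  norm <- if (anyNA(gc_fraction)) {
    gc_normalize(norm, gc_aug, gc_bins = config$gc_bins)
  } else {
    withCallingHandlers(
      gc_normalize(norm, gc_aug, gc_bins = config$gc_bins),
      warning = function(w) {
        if (grepl("GC fraction missing", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  list(values = norm[-nrow(norm), , drop = FALSE],
       theta = norm[nrow(norm), ])
}

#' Open/closed call for an accessibility value
#'
#' An element (or gene) is open in a cell iff its normalized value is
#' strictly above the cell's threshold. A value exactly at the threshold is
#' closed.
#'
#' @param value Normalized accessibility value(s).
#' @param theta Matching threshold value(s).
#' @return Logical vector/matrix.
#' @export
call_open <- function(value, theta) {
  value > theta
}

#' Gene-level accessibility from element values
#'
#' The gene value is the maximum over its promoter's and linked enhancers'
#' values: the gene open call is then exactly the OR of its elements' open
#' calls, mirroring the rule that a gene is accessible if any of its
#' regulatory elements is open. Unlinked enhancers are excluded. Genes
#' listed in `genes` without any linked element get value `fill` with a
#' warning.
#'
#' @param values Elements-by-cells numeric matrix (rows named by element id).
#' @param elements `regulatory_elements` data.frame linking elements to genes.
#' @param genes Optional character vector fixing the output gene universe
#'   and order; defaults to all linked genes.
#' @param fill Value assigned to genes with no linked element (default 0).
#' @return Genes-by-cells numeric matrix.
#' @export
gene_accessibility <- function(values, elements, genes = NULL, fill = 0) {
  pairs <- element_gene_pairs(elements)
  pairs <- pairs[pairs$element %in% rownames(values), , drop = FALSE]
  if (is.null(genes)) genes <- unique(pairs$gene)
  out <- matrix(fill, nrow = length(genes), ncol = ncol(values),
                dimnames = list(genes, colnames(values)))
  pairs <- pairs[pairs$gene %in% genes, , drop = FALSE]
  orphan <- setdiff(genes, pairs$gene)
  if (length(orphan)) {
    warning(length(orphan), " gene(s) have no linked regulatory element; ",
            "assigned value ", fill, call. = FALSE)
  }
  gi <- match(pairs$gene, genes)
  ei <- match(pairs$element, rownames(values))
  ord <- order(gi)
  gi <- gi[ord]; ei <- ei[ord]
  grp <- split(ei, gi)
  for (k in names(grp)) {
    rows <- grp[[k]]
    out[as.integer(k), ] <- if (length(rows) == 1L) values[rows, ]
                            else do.call(pmax, lapply(rows, function(r) values[r, ]))
  }
  out
}

#' Sigmoid gene activity
#'
#' Maps a gene accessibility value to a probability of expression:
#' `1 / (1 + exp(-k * (value - theta)))`. Monotone increasing in the value,
#' decreasing in the threshold; the activity exceeds 0.5 exactly when the
#' strict open call is true, and equals 0.5 at the threshold.
#'
#' @param value Gene accessibility value(s) (matrix or vector).
#' @param theta Threshold value(s), recycled along cells.
#' @param k Sigmoid steepness (> 0).
#' @return Activities in (0, 1), same shape as `value`.
#' @export
sigmoid_activity <- function(value, theta, k) {
  assert_that(k > 0, "sigmoid_k must be > 0")
  1 / (1 + exp(-k * (value - theta)))
}

#' Auto-calibrate the sigmoid steepness
#'
#' `k = 4 / median(positive (value - theta) gaps)`, so the median open
#' element maps to an activity of about 0.982 and a typical open element to
#' about 0.88, keeping activities informative across sequencing depths.
#' Falls back to `k = 1` (with a warning) when no gap is positive.
#'
#' @param margins Numeric values of `value - theta` (matrix or vector).
#' @return Scalar k > 0.
#' @export
calibrate_sigmoid_k <- function(margins) {
  pos <- margins[margins > 0]
  if (!length(pos)) {
    warning("no element exceeds its threshold; sigmoid_k falls back to 1",
            call. = FALSE)
    return(1)
  }
  4 / stats::median(pos)
}
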