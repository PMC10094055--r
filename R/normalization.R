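# Smooth quantile normalization across cells and GC-content conditional
# normalization across elements.

#' Smooth quantile normalization across cells
#'
#' A group-aware quantile normalization: per rank k, the reference value for
#' a cell in group g is `w_k * Q_g(k) + (1 - w_k) * Q(k)`, where `Q_g` is the
#' group-mean sorted value, `Q` the global mean sorted value, and
#' `w_k` the fraction of that rank's across-cell variance explained by the
#' grouping (clamped to \[0,1\]). Ranks that differ only weakly between
#' groups are pulled to the common reference; ranks where groups genuinely
#' differ keep their group-specific quantiles. With a single group (or
#' identical group distributions) this reduces to classical quantile
#' normalization. Ties within a cell receive the mean of the blended
#' reference over their rank range. Groups with a single cell use the global
#' reference (with a message).
#'
#' @param m Elements-by-cells matrix (sparse or dense) with cell colnames.
#' @param groups Named character vector mapping every cell to a group label.
#' @return Dense numeric matrix of the same shape; within each cell, value
#'   ranks equal raw ranks (ties allowed).
#' @export
smooth_quantile_normalize <- function(m, groups) {
  X <- as.matrix(m)
  n <- ncol(X)
  assert_that(n >= 2, "smooth quantile normalization needs >= 2 cells")
  assert_that(!is.null(colnames(X)), "matrix must have cell colnames")
  g <- unname(groups[colnames(X)])
  assert_that(!anyNA(g), "every cell must have a group label")

  Xs <- apply(X, 2, sort, method = "radix")      # ranks x cells
  q_global <- rowMeans(Xs)
  levs <- unique(g)
  sizes <- vapply(levs, function(l) sum(g == l), 0L)
  singletons <- levs[sizes == 1L]
  if (length(singletons)) {
    message(length(singletons),
            " group(s) with a single cell use the global reference")
  }
  q_grp <- vapply(levs, function(l) rowMeans(Xs[, g == l, drop = FALSE]),
                  numeric(nrow(Xs)))
  ss_total <- rowSums((Xs - q_global)^2)
  ss_between <- as.vector((q_grp - q_global)^2 %*% sizes)
  w <- ifelse(ss_total > 0, pmin(pmax(ss_between / ss_total, 0), 1), 0)

  out <- X
  for (jj in seq_len(n)) {
    lev <- g[jj]
    ref <- if (lev %in% singletons) q_global
           else w * q_grp[, lev] + (1 - w) * q_global
    r <- rank(X[, jj], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, jj] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' GC-content conditional normalization across elements
#'
#' Elements are binned into equal-frequency GC bins; within each bin, values
#' are rescaled per cell so the bin's per-cell mean equals the per-cell mean
#' over all GC-annotated elements. This removes a first-order GC coverage
#' bias while preserving rank order within each bin per cell. Bins with
#' fewer than `min_per_bin` elements are merged with the nearest bin.
#' Elements with missing GC are passed through unscaled; if all GC values
#' are missing the transform is the identity (with a warning).
#'
#' @param m Elements-by-cells numeric matrix.
#' @param gc_fraction Numeric vector of GC fractions per element (NA allowed).
#' @param gc_bins Number of equal-frequency bins (default 10).
#' @param min_per_bin Minimum elements per bin before merging (default 5).
#' @return Matrix of the same shape with per-bin per-cell means equalized.
#' @export
gc_normalize <- function(m, gc_fraction, gc_bins = 10L, min_per_bin = 5L) {
  X <- as.matrix(m)
  assert_that(length(gc_fraction) == nrow(X),
              "gc_fraction must have one value per element (row)")
  has_gc <- !is.na(gc_fraction)
  if (!any(has_gc)) {
    warning("all GC fractions missing: GC normalization is the identity",
            call. = FALSE)
    return(X)
  }
  if (mean(has_gc) < 0.9) {
    warning(sprintf("GC fraction missing for %.0f%% of elements; those are passed through unscaled",
                    100 * mean(!has_gc)), call. = FALSE)
  }
  gc <- gc_fraction[has_gc]
  nb <- max(1L, min(as.integer(gc_bins), length(unique(gc))))
  brk <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = nb + 1)))
  bin <- if (length(brk) > 2) {
    as.integer(cut(gc, breaks = brk, include.lowest = TRUE))
  } else rep(1L, length(gc))
  # merge undersized bins with the nearest (adjacent) bin
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab))[tab < min_per_bin]
    if (!length(small) || length(tab) == 1) break
    b <- small[1]
    others <- setdiff(as.integer(names(tab)), b)
    bin[bin == b] <- others[which.min(abs(others - b))]
    bin <- as.integer(factor(bin))
  }

  sub <- X[has_gc, , drop = FALSE]
  global_mean <- colMeans(sub)
  out <- X
  for (b in unique(bin)) {
    rows <- which(has_gc)[bin == b]
    bin_mean <- colMeans(X[rows, , drop = FALSE])
    f <- ifelse(bin_mean > 0 & global_mean > 0, global_mean / bin_mean, 1)
    out[rows, ] <- sweep(X[rows, , drop = FALSE], 2, f, `*`)
  }
  out
}
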