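# Evaluation protocols: marker-based TPR/FPR, bulk-profile test,
# expression-stratified 1-F1 imputation error, and gene-gene correlation
# preservation under simulated dropout.
#
# "Non-zero" after imputation means strictly positive at tolerance exactly 0:
# in the additive design any positive value is an expression call.

rate_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Marker-based TPR/FPR
#'
#' Over entries (gene, cell) where the gene is a positive surface marker for
#' the cell's type and the ground truth is non-zero: TP if imputed non-zero,
#' FN if imputed zero. Over entries where the gene is a negative marker for
#' the cell's type and the ground truth is zero: FP if imputed non-zero, TN
#' if imputed zero. `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)`. Markers absent
#' from the matrix are skipped with a message. An empty positive or negative
#' entry set yields `NA` (never 0 by convention).
#'
#' @param imputed Imputed genes-by-cells matrix.
#' @param truth Ground-truth matrix: the pre-dropout matrix when available,
#'   else the raw matrix.
#' @param markers Named list per type with `positive`/`negative` gene ids
#'   (see [read_markers()]).
#' @param annotation Named character vector: cell -> type.
#' @return List with pooled `tpr`, `fpr`, the four counts, and a `per_type`
#'   data.frame.
#' @export
marker_test <- function(imputed, truth, markers, annotation) {
  validate_annotation(annotation)
  I <- as.matrix(imputed)
  Tm <- as.matrix(truth)
  labels <- unname(annotation[colnames(I)])
  per <- lapply(names(markers), function(t) {
    cols <- which(labels == t)
    if (!length(cols)) return(NULL)
    pos <- intersect(markers[[t]]$positive, rownames(I))
    neg <- intersect(markers[[t]]$negative, rownames(I))
    skipped <- length(markers[[t]]$positive) - length(pos) +
      length(markers[[t]]$negative) - length(neg)
    if (skipped > 0) message(skipped, " marker(s) absent from matrix for type ", t)
    tp <- fn <- fp <- tn <- 0L
    if (length(pos)) {
      truthy <- Tm[pos, cols, drop = FALSE] > 0
      imp <- I[pos, cols, drop = FALSE] > 0
      tp <- sum(imp & truthy); fn <- sum(!imp & truthy)
    }
    if (length(neg)) {
      zero <- Tm[neg, cols, drop = FALSE] == 0
      imp <- I[neg, cols, drop = FALSE] > 0
      fp <- sum(imp & zero); tn <- sum(!imp & zero)
    }
    data.frame(type = t, tp = tp, fn = fn, fp = fp, tn = tn,
               tpr = rate_or_na(tp, tp + fn), fpr = rate_or_na(fp, fp + tn))
  })
  per <- do.call(rbind, per)
  list(tpr = rate_or_na(sum(per$tp), sum(per$tp) + sum(per$fn)),
       fpr = rate_or_na(sum(per$fp), sum(per$fp) + sum(per$tn)),
       tp = sum(per$tp), fn = sum(per$fn), fp = sum(per$fp), tn = sum(per$tn),
       per_type = per)
}

#' Bulk-profile TPR/FPR
#'
#' Defines, per cell type, the positive class as the `top_fraction` most
#' expressed genes in the matching bulk profile and the negative class as
#' genes with bulk value 0, then computes TPR/FPR as in [marker_test()] over
#' all cells of the type. A pseudo-bulk from [pseudo_bulk()] on the synthetic
#' truth serves as the bulk profile when no external bulk data exist.
#'
#' @param imputed Imputed genes-by-cells matrix.
#' @param truth Ground-truth matrix (pre-dropout when available, else raw).
#' @param bulk_profile Genes-by-types numeric matrix of bulk expression.
#' @param annotation Named character vector: cell -> type.
#' @param top_fraction Fraction of genes forming the positive class
#'   (default 0.10; must be > 0).
#' @return As [marker_test()].
#' @export
bulk_test <- function(imputed, truth, bulk_profile, annotation,
                      top_fraction = 0.10) {
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "top_fraction must be in (0, 1]")
  genes <- intersect(rownames(imputed), rownames(bulk_profile))
  assert_that(length(genes) > 0, "no overlap between matrix and bulk profile")
  markers <- lapply(colnames(bulk_profile), function(t) {
    v <- bulk_profile[genes, t]
    n_top <- max(1L, round(top_fraction * length(genes)))
    list(positive = genes[order(v, decreasing = TRUE)[seq_len(n_top)]],
         negative = genes[v == 0])
  })
  names(markers) <- colnames(bulk_profile)
  marker_test(imputed, truth, markers, annotation)
}

#' Expression-stratified imputation error (1 - F1)
#'
#' Recovery of simulated dropouts stratified by the true expression level of
#' the masked entry. Default strata are the quartiles of the masked true
#' values, with the lowest stratum anchored at 0 so that true-zero entries
#' (the false-positive candidates) belong to it. Per stratum: recall is the
#' fraction of masked entries imputed non-zero; precision is the fraction of
#' imputed-non-zero entries among the stratum's true-zero + masked entries
#' that are genuinely masked; the error is 1 minus their harmonic mean (F1).
#' An empty stratum is reported as `NA`.
#'
#' @param imputed Imputed genes-by-cells matrix.
#' @param truth Pre-dropout genes-by-cells matrix.
#' @param mask Dropout mask from [inject_dropouts()]; must be non-empty.
#' @param breaks Optional numeric vector of stratum boundaries (inner
#'   breakpoints); defaults to the 25/50/75% quantiles of masked true values.
#' @return List with `per_stratum` data.frame (bounds, recall, precision,
#'   error) and pooled `overall` error.
#' @export
stratified_error <- function(imputed, truth, mask, breaks = NULL) {
  assert_that(nrow(mask) > 0, "dropout mask is empty")
  I <- as.matrix(imputed)
  Tm <- as.matrix(truth)
  if (is.null(breaks)) {
    breaks <- unique(stats::quantile(mask$value, c(0.25, 0.5, 0.75)))
  }
  bounds <- unique(c(0, breaks, Inf))
  mi <- cbind(match(mask$gene, rownames(I)), match(mask$cell, colnames(I)))
  assert_that(!anyNA(mi), "mask references genes/cells absent from the matrix")
  masked_imp <- I[mi] > 0
  stratum_of_mask <- findInterval(mask$value, bounds, left.open = FALSE)

  zero_fp <- sum(I[Tm == 0] > 0)   # true-zero entries imputed non-zero
  n_strata <- length(bounds) - 1
  per <- lapply(seq_len(n_strata), function(s) {
    in_s <- stratum_of_mask == s
    n <- sum(in_s)
    tp <- sum(masked_imp[in_s])
    fp <- if (s == 1) zero_fp else 0
    if (n == 0) {
      return(data.frame(lower = bounds[s], upper = bounds[s + 1],
                        n = 0L, recall = NA_real_, precision = NA_real_,
                        error = NA_real_))
    }
    recall <- tp / n
    precision <- rate_or_na(tp, tp + fp)
    f1 <- if (is.na(precision) || (precision + recall) == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(lower = bounds[s], upper = bounds[s + 1], n = n,
               recall = recall, precision = precision, error = 1 - f1)
  })
  per <- do.call(rbind, per)
  tp_all <- sum(masked_imp)
  recall_all <- tp_all / nrow(mask)
  precision_all <- rate_or_na(tp_all, tp_all + zero_fp)
  f1_all <- if (is.na(precision_all) || (precision_all + recall_all) == 0) 0
            else 2 * precision_all * recall_all / (precision_all + recall_all)
  list(per_stratum = per, overall = 1 - f1_all)
}

#' Gene-gene correlation preservation
#'
#' Pearson correlation per gene pair per matrix, compared against a reference
#' correlation (e.g. one measured by an orthogonal assay such as RNA FISH).
#' By default r is computed over cells with at least one non-zero value in
#' the pair; `cells = "all"` uses every cell. The preservation score is
#' `|r - reference_r|`. Pairs with a zero-variance gene yield `NA`.
#'
#' @param matrices Named list of genes-by-cells matrices (e.g. raw, dropout,
#'   imputed).
#' @param gene_pairs Data.frame (or 2-column matrix) of gene id pairs.
#' @param reference_r Numeric vector of reference correlations, one per pair.
#' @param cells `"nonzero_any"` (default) or `"all"`.
#' @param min_cells Minimum retained cells required to report r (default 3).
#' @return Data.frame: pair genes, matrix name, `n_cells`, `r`,
#'   `reference_r`, `abs_dev`.
#' @export
correlation_preservation <- function(matrices, gene_pairs, reference_r,
                                     cells = c("nonzero_any", "all"),
                                     min_cells = 3L) {
  cells <- match.arg(cells)
  gene_pairs <- as.data.frame(gene_pairs)
  assert_that(length(reference_r) == nrow(gene_pairs),
              "reference_r must have one value per gene pair")
  assert_that(!is.null(names(matrices)), "matrices must be a named list")
  rows <- list()
  for (p in seq_len(nrow(gene_pairs))) {
    g1 <- as.character(gene_pairs[p, 1]); g2 <- as.character(gene_pairs[p, 2])
    for (nm in names(matrices)) {
      M <- matrices[[nm]]
      if (!all(c(g1, g2) %in% rownames(M))) {
        rows[[length(rows) + 1]] <- data.frame(
          gene1 = g1, gene2 = g2, matrix = nm, n_cells = 0L,
          r = NA_real_, reference_r = reference_r[p], abs_dev = NA_real_)
        next
      }
      x <- as.numeric(M[g1, ]); y <- as.numeric(M[g2, ])
      if (cells == "nonzero_any") {
        keep <- x > 0 | y > 0
        x <- x[keep]; y <- y[keep]
      }
      r <- if (length(x) >= min_cells &&
               stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y)
           else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        gene1 = g1, gene2 = g2, matrix = nm, n_cells = length(x), r = r,
        reference_r = reference_r[p],
        abs_dev = abs(r - reference_r[p]))
    }
  }
  do.call(rbind, rows)
}

#' Run the full dropout benchmark on a synthetic dataset
#'
#' For each requested dropout rate: injects dropouts into the true expression
#' matrix, runs the accessibility-based imputation, and scores the marker
#' test, bulk test, stratified imputation error, and (when the dataset embeds
#' a correlated gene pair) correlation preservation.
#'
#' @param sim A [simulate_dataset()] result.
#' @param rates Dropout rates (default the 25/50/75/95% grid).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the dropout injection.
#' @return List of class `benchmark_result`, one entry per rate, each with
#'   `marker`, `bulk`, `error`, and `correlation` components.
#' @export
run_benchmark <- function(sim, rates = c(0.25, 0.5, 0.75, 0.95),
                          config = pipeline_config(), seed = 1L) {
  assert_that(all(rates >= 0 & rates < 1), "dropout rates must be in [0, 1)")
  truth <- sim$expression
  bulk <- pseudo_bulk(truth, sim$rna_annotation)
  pair <- sim$truth$correlated_pair
  ref_r <- if (length(pair)) {
    stats::cor(as.numeric(truth[pair[1], ]), as.numeric(truth[pair[2], ]))
  } else NULL
  out <- lapply(rates, function(rate) {
    dd <- inject_dropouts(truth, rate, sim$rna_annotation, seed = seed,
                          strata = config$lhs_strata)
    res <- epi_impute(dd$matrix, sim$rna_annotation, sim$fragments,
                      sim$atac_annotation, sim$promoters, sim$enhancers,
                      blacklist = sim$blacklist, config = config)
    corr <- if (length(pair)) {
      correlation_preservation(
        list(raw = truth, dropout = dd$matrix, imputed = res$imputed),
        data.frame(gene1 = pair[1], gene2 = pair[2]), ref_r)
    } else NULL
    list(rate = rate,
         marker = marker_test(res$imputed, truth, sim$truth$marker_sets,
                              sim$rna_annotation),
         bulk = bulk_test(res$imputed, truth, bulk, sim$rna_annotation),
         error = stratified_error(res$imputed, truth, dd$mask),
         correlation = corr)
  })
  names(out) <- paste0("rate_", rates)
  structure(out, class = "benchmark_result")
}
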