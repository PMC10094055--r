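# The imputation core: per-population aggregation of gene activity and the
# additive update of the expression matrix, plus the end-to-end pipeline.

#' Aggregate gene activity per cell population
#'
#' Entry (g, t) is the median over cells of type t of the gene activity.
#' For an even number of cells the median is the mean of the two middle
#' values. With `binarize = TRUE`, activities are first hard-thresholded at
#' 0.5 (equivalently, the strict open call) so the aggregate is the median
#' open state of the population; the pipeline default uses this mode (see
#' [epi_impute()]), so a gene closed across a population contributes exactly
#' 0 and never converts true zeros into spurious expression.
#'
#' @param activity Genes-by-cells activity matrix (values in \[0,1\]).
#' @param annotation Named character vector: ATAC cell -> cell-type label.
#'   Labels with zero cells in the matrix are dropped with a warning.
#' @param binarize Threshold activities at 0.5 before taking the median
#'   (default `FALSE`: continuous median).
#' @return Genes-by-types matrix with values in \[0,1\].
#' @export
aggregate_population_activity <- function(activity, annotation,
                                          binarize = FALSE) {
  validate_annotation(annotation)
  cells <- colnames(activity)
  assert_that(all(cells %in% names(annotation)), "every ATAC cell must be annotated")
  labels <- unname(annotation[cells])
  types <- unique(unname(annotation))
  empty <- setdiff(types, labels)
  if (length(empty)) {
    warning("label(s) with no cells in the activity matrix dropped: ",
            paste(empty, collapse = ", "), call. = FALSE)
    types <- setdiff(types, empty)
  }
  A <- as.matrix(activity)
  if (binarize) A <- (A > 0.5) + 0
  out <- vapply(types, function(t) {
    apply(A[, labels == t, drop = FALSE], 1, stats::median)
  }, numeric(nrow(A)))
  dimnames(out) <- list(rownames(activity), types)
  out
}

#' Add population activity to expression counts
#'
#' `imputed(g, c) = raw(g, c) + scale * pop_activity(g, type(c))`: each cell
#' receives the aggregate activity of its own population, so dropouts of
#' genes accessible in that population become non-zero while the raw counts
#' are never reduced and within-type expression order is preserved. Genes
#' absent from the activity matrix and cells whose label has no ATAC
#' population pass through unchanged (tallied in attributes
#' `n_unmatched_genes` / `n_unmatched_cells`).
#'
#' @param expression Genes-by-cells count matrix (dgCMatrix or dense).
#' @param pop_activity Genes-by-types matrix from
#'   [aggregate_population_activity()].
#' @param annotation Named character vector: RNA cell -> cell-type label.
#' @param scale Multiplier for the additive activity term (default 1: the
#'   raw probability is added, on the \[0,1\] scale).
#' @return Sparse genes-by-cells matrix with fractional values;
#'   elementwise >= the input.
#' @export
impute_expression <- function(expression, pop_activity, annotation, scale = 1) {
  expression <- validate_expression(as_dgc(expression))
  validate_annotation(annotation)
  cells <- colnames(expression)
  assert_that(all(cells %in% names(annotation)), "every RNA cell must be annotated")
  genes <- intersect(rownames(expression), rownames(pop_activity))
  assert_that(length(genes) > 0,
              "no overlapping genes between expression and activity matrices")
  labels <- unname(annotation[cells])
  matched_cells <- labels %in% colnames(pop_activity)

  add <- pop_activity[genes, , drop = FALSE] * scale
  gi <- match(genes, rownames(expression))
  # additive term per gene x cell, constant within a cell type
  block <- matrix(0, nrow = nrow(expression), ncol = ncol(expression))
  block[gi, matched_cells] <- add[, labels[matched_cells], drop = FALSE]
  out <- as_dgc(expression + block)
  dimnames(out) <- dimnames(expression)
  attr(out, "n_unmatched_genes") <- nrow(expression) - length(genes)
  attr(out, "n_unmatched_cells") <- sum(!matched_cells)
  out
}

#' Run the full accessibility-based imputation pipeline
#'
#' Orchestrates the stages: Tn5 shift, promoter/enhancer window counting,
#' blacklist-based threshold vector, smooth quantile + GC normalization
#' (promoter and enhancer matrices separately, each with the threshold
#' carried through as a pseudo-element), gene-level accessibility (max over
#' elements of the value-minus-threshold margin, so the gene open call is
#' the OR over elements), sigmoid activity, per-population median
#' aggregation, and the additive imputation.
#'
#' @param expression Genes-by-cells count matrix or a path readable by
#'   [read_expression()].
#' @param rna_annotation Named character vector or TSV path: RNA barcode ->
#'   cell-type label.
#' @param fragments Fragments data.frame or path (see [read_fragments()]).
#' @param atac_annotation Named character vector or TSV path: ATAC barcode ->
#'   label. RNA and ATAC barcodes are distinct namespaces; modalities are
#'   matched only through these labels.
#' @param promoters `regulatory_elements` data.frame or BED path (promoter
#'   TSS records).
#' @param enhancers Optional `regulatory_elements` data.frame or BED path.
#' @param links Optional enhancer-gene links (used only when `enhancers` is
#'   a path).
#' @param blacklist Blacklist intervals data.frame or BED path.
#' @param config A [pipeline_config()].
#' @param fragments_shifted Set `TRUE` when the fragments file already
#'   carries Tn5 offsets (ignored when `fragments` is a data.frame from
#'   [read_fragments()], which records the flag itself).
#' @param binarize_before_median Hard-threshold activities at 0.5 before the
#'   per-type median (default `TRUE`, matching the binarized gene activity
#'   aggregation; set `FALSE` to aggregate continuous probabilities).
#' @param gc Optional GC fractions for elements given as BED paths (see
#'   [read_bed_elements()]).
#' @return List of class `epi_impute_result`: `imputed` (sparse matrix),
#'   `activity` (genes-by-cells, in (0,1)), `pop_activity`
#'   (genes-by-types), `margins` (gene accessibility minus threshold),
#'   `theta` (raw per-cell thresholds), `sigmoid_k`, and `log` (counters of
#'   dropped/unmatched entities).
#' @export
epi_impute <- function(expression, rna_annotation, fragments, atac_annotation,
                       promoters, enhancers = NULL, links = NULL, blacklist,
                       config = pipeline_config(), fragments_shifted = FALSE,
                       binarize_before_median = TRUE, gc = NULL) {
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
  if (is_path(expression)) expression <- read_expression(expression)
  if (is_path(rna_annotation)) rna_annotation <- read_cell_annotation(rna_annotation)
  if (is_path(atac_annotation)) atac_annotation <- read_cell_annotation(atac_annotation)
  if (is.character(fragments)) fragments <- read_fragments(fragments, shifted = fragments_shifted)
  if (is.character(promoters)) promoters <- read_bed_elements(promoters, "promoter", gc = gc)
  if (is.character(enhancers)) enhancers <- read_bed_elements(enhancers, "enhancer", links = links, gc = gc)
  if (is.character(blacklist)) blacklist <- read_blacklist(blacklist)
  expression <- validate_expression(as_dgc(expression))
  validate_annotation(rna_annotation)
  validate_annotation(atac_annotation)

  frags <- tn5_shift(fragments, config)
  atac_cells <- names(atac_annotation)
  theta <- build_threshold_vector(
    blacklist_coverage(frags, blacklist, atac_cells, config), config)

  element_sets <- list(promoter = promoters)
  if (!is.null(enhancers) && nrow(enhancers) > 0) element_sets$enhancer <- enhancers

  margin_list <- list()
  unmatched <- 0L
  for (kind in names(element_sets)) {
    els <- element_windows(element_sets[[kind]], config)
    counts <- count_fragments(frags, els, atac_cells, config)
    unmatched <- max(unmatched, attr(counts, "n_unmatched_barcodes") %||% 0L)
    norm <- normalize_with_threshold(counts, theta, atac_annotation,
                                     els$gc_fraction, config)
    margin_list[[kind]] <- list(
      margins = sweep(norm$values, 2, norm$theta, `-`),
      elements = els)
  }

  genes_atac <- unique(unlist(lapply(margin_list, function(x)
    element_gene_pairs(x$elements)$gene)))
  gene_margin <- NULL
  for (x in margin_list) {
    gm <- suppressWarnings(
      gene_accessibility(x$margins, x$elements, genes = genes_atac, fill = -Inf))
    gene_margin <- if (is.null(gene_margin)) gm else pmax(gene_margin, gm)
  }
  gene_margin[!is.finite(gene_margin)] <- 0  # genes with no element anywhere

  k <- config$sigmoid_k %||% calibrate_sigmoid_k(gene_margin)
  activity <- sigmoid_activity(gene_margin, 0, k)
  pop <- aggregate_population_activity(activity, atac_annotation,
                                       binarize = binarize_before_median)
  imputed <- impute_expression(expression, pop, rna_annotation)

  structure(list(
    imputed = imputed,
    activity = activity,
    pop_activity = pop,
    margins = gene_margin,
    theta = theta,
    sigmoid_k = k,
    log = list(
      n_malformed_fragments = attr(fragments, "malformed") %||% 0L,
      n_dropped_shift = attr(frags, "n_dropped_shift") %||% 0L,
      n_unmatched_barcodes = unmatched,
      n_unmatched_genes = attr(imputed, "n_unmatched_genes"),
      n_unmatched_cells = attr(imputed, "n_unmatched_cells"))
  ), class = "epi_impute_result")
}

#' @export
print.epi_impute_result <- function(x, ...) {
  cat("epi_impute result\n")
  cat(sprintf("  imputed matrix : %d genes x %d cells\n",
              nrow(x$imputed), ncol(x$imputed)))
  cat(sprintf("  populations    : %s\n",
              paste(colnames(x$pop_activity), collapse = ", ")))
  cat(sprintf("  sigmoid k      : %.4g\n", x$sigmoid_k))
  cat(sprintf("  unmatched      : %d genes, %d cells, %d ATAC barcodes\n",
              x$log$n_unmatched_genes, x$log$n_unmatched_cells,
              x$log$n_unmatched_barcodes))
  invisible(x)
}
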