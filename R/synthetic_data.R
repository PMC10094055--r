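# Matched scRNA-seq + scATAC-seq simulator with known ground truth, and the
# Latin-hypercube dropout injector used by the benchmark harness.

#' Design of a synthetic matched dataset
#'
#' Describes a multi-population experiment in which each cell type carries
#' designated positive surface-marker genes (expressed only in that type) and
#' negative markers (silent in that type, drawn from the positive markers of
#' other types), a shared block of background genes expressed across all
#' types, a fraction of fully silent genes, and an optional housekeeping gene
#' pair with a prescribed latent Pearson correlation (Gaussian copula over
#' negative-binomial marginals). Expression counts are NB(mean, dispersion)
#' with variance `mu + mu^2 / dispersion`. ATAC fragments pile up at the
#' regulatory elements (one promoter and one linked enhancer per gene) of
#' genes expressed in each type (Poisson per open element per cell, placed
#' uniformly within the counting window), on top of a uniform Poisson
#' background covering the whole synthetic genome including one blacklist
#' region per chromosome. The synthetic genome tiles one chromosome per
#' `genes_per_chrom` genes at fixed spacing, alternating gene strands.
#'
#' @param n_cell_types Number of cell types (default 3).
#' @param cells_per_type Cells per type in both modalities (default 200).
#' @param n_genes Total genes (default 1500).
#' @param markers_per_type Positive markers per type (default 20).
#' @param negative_markers_per_type Negative markers per type (default 20).
#' @param marker_mean NB mean of a positive marker in its own type (default 10).
#' @param background_expressed_fraction Fraction of non-marker genes expressed
#'   in all types (default 0.7; the rest are silent everywhere).
#' @param background_meanlog,background_sdlog Log-normal parameters of
#'   background gene means (defaults `log(6)` and 0.6).
#' @param nb_dispersion NB dispersion (size) parameter (default 2).
#' @param correlated_pair `NULL`, or a list with `rho` (latent Pearson
#'   correlation), `mean` and `dispersion` for one housekeeping gene pair
#'   expressed in every type (default rho 0.7, mean 20, dispersion 50).
#' @param atac_signal_fragments Mean fragments per open element per cell
#'   (default 3; an idealized deeply-covered, concordant ATAC experiment).
#' @param atac_noise_rate Background fragments per kb per cell over the whole
#'   genome, blacklist included (default 0.2).
#' @param fragment_length Fragment length in bp (default 50).
#' @param genes_per_chrom Genes per synthetic chromosome (default 500).
#' @param gene_spacing Distance between consecutive TSSs in bp (default 5000).
#' @param enhancer_offset,enhancer_width Enhancer placement relative to the
#'   TSS and its width in bp (defaults 3000 and 300).
#' @param blacklist_width Width of the per-chromosome blacklist region in bp
#'   (default 50000).
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return List of class `synthetic_design`.
#' @export
synthetic_design <- function(n_cell_types = 3L, cells_per_type = 200L,
                             n_genes = 1500L, markers_per_type = 20L,
                             negative_markers_per_type = 20L,
                             marker_mean = 10,
                             background_expressed_fraction = 0.7,
                             background_meanlog = log(6),
                             background_sdlog = 0.6,
                             nb_dispersion = 2,
                             correlated_pair = list(rho = 0.7, mean = 20,
                                                    dispersion = 50),
                             atac_signal_fragments = 3,
                             atac_noise_rate = 0.2,
                             fragment_length = 50L,
                             genes_per_chrom = 500L, gene_spacing = 5000L,
                             enhancer_offset = 3000L, enhancer_width = 300L,
                             blacklist_width = 50000L, seed = 1L) {
  assert_that(markers_per_type * n_cell_types <= n_genes,
              "markers_per_type x n_cell_types exceeds n_genes")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(atac_noise_rate >= 0 && atac_signal_fragments >= 0,
              "ATAC rates must be >= 0")
  structure(as.list(environment()), class = "synthetic_design")
}

# synthetic genome layout: gene table + elements + blacklist
synthetic_annotation <- function(design) {
  n <- design$n_genes
  gene <- sprintf("gene%04d", seq_len(n))
  chrom_i <- ((seq_len(n) - 1L) %/% design$genes_per_chrom) + 1L
  pos_i <- ((seq_len(n) - 1L) %% design$genes_per_chrom)
  tss <- 2000L + pos_i * design$gene_spacing
  strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
  chrom <- paste0("chrS", chrom_i)
  genes <- data.frame(gene = gene, chrom = chrom, tss = tss, strand = strand,
                      stringsAsFactors = FALSE)

  prom <- data.frame(id = paste0("prom_", gene), chrom = chrom, start = tss,
                     end = tss + 1L, strand = strand, kind = "promoter",
                     gc_fraction = round(stats::runif(n, 0.35, 0.65), 4),
                     linked = TRUE, stringsAsFactors = FALSE)
  prom$gene_ids <- as.list(gene)
  prom <- new_regulatory_elements(prom)

  enh <- data.frame(id = paste0("enh_", gene), chrom = chrom,
                    start = tss + design$enhancer_offset,
                    end = tss + design$enhancer_offset + design$enhancer_width,
                    strand = ".", kind = "enhancer",
                    gc_fraction = round(stats::runif(n, 0.35, 0.65), 4),
                    linked = TRUE, stringsAsFactors = FALSE)
  enh$gene_ids <- as.list(gene)
  enh <- new_regulatory_elements(enh)

  n_chrom <- max(chrom_i)
  chrom_len <- 2000L + design$genes_per_chrom * design$gene_spacing +
    design$blacklist_width + 10000L
  blacklist <- data.frame(
    chrom = paste0("chrS", seq_len(n_chrom)),
    start = chrom_len - design$blacklist_width - 5000L,
    end = chrom_len - 5000L, stringsAsFactors = FALSE)
  list(genes = genes, promoters = prom, enhancers = enh,
       blacklist = blacklist,
       chrom_len = stats::setNames(rep(chrom_len, n_chrom),
                                   paste0("chrS", seq_len(n_chrom))))
}

# genes x types matrix of NB means plus marker bookkeeping
synthetic_means <- function(design) {
  n <- design$n_genes
  types <- paste0("type", seq_len(design$n_cell_types))
  gene <- sprintf("gene%04d", seq_len(n))
  mu <- matrix(0, n, design$n_cell_types, dimnames = list(gene, types))

  pos <- lapply(seq_len(design$n_cell_types), function(t) {
    idx <- (t - 1L) * design$markers_per_type + seq_len(design$markers_per_type)
    mu[idx, t] <<- design$marker_mean
    gene[idx]
  })
  names(pos) <- types
  neg <- lapply(seq_len(design$n_cell_types), function(t) {
    others <- unlist(pos[-t], use.names = FALSE)
    sample(others, min(design$negative_markers_per_type, length(others)))
  })
  names(neg) <- types

  used <- design$n_cell_types * design$markers_per_type
  pair_genes <- character(0)
  if (!is.null(design$correlated_pair)) {
    pair_genes <- gene[used + 1:2]
    mu[pair_genes, ] <- design$correlated_pair$mean
    used <- used + 2L
  }
  rest <- if (used < n) gene[(used + 1L):n] else character(0)
  expressed <- sort(sample(rest, round(design$background_expressed_fraction *
                                         length(rest))))
  if (length(expressed)) {
    mu[expressed, ] <- stats::rlnorm(length(expressed),
                                     design$background_meanlog,
                                     design$background_sdlog)
  }
  list(mu = mu, positive = pos, negative = neg, pair = pair_genes)
}

#' Generate a matched synthetic scRNA-seq + scATAC-seq dataset
#'
#' Draws expression counts, ATAC fragments, regulatory annotation, blacklist
#' regions and cell annotations for both modalities from a
#' [synthetic_design()]. RNA and ATAC barcodes live in distinct namespaces
#' (`rna_*`, `atac_*`); the modalities share only the cell-type labels.
#' Fully reproducible: the same design (including its seed) gives identical
#' output.
#'
#' @param design A [synthetic_design()].
#' @return List of class `synthetic_dataset` with `expression` (dgCMatrix,
#'   pre-dropout truth), `fragments` (unshifted, 10x-style count column),
#'   `promoters`, `enhancers`, `blacklist`, `rna_annotation`,
#'   `atac_annotation`, and `truth` (design, marker sets, per-type open
#'   element ids, the correlated pair, genes-by-types true means).
#' @export
simulate_dataset <- function(design = synthetic_design()) {
  withr::with_seed(design$seed, {
    ann <- synthetic_annotation(design)
    mm <- synthetic_means(design)
    types <- colnames(mm$mu)
    n_cells <- design$cells_per_type * design$n_cell_types
    rna_cells <- sprintf("rna_%s_c%03d", rep(types, each = design$cells_per_type),
                         rep(seq_len(design$cells_per_type), design$n_cell_types))
    atac_cells <- sub("^rna_", "atac_", rna_cells)
    rna_ann <- stats::setNames(rep(types, each = design$cells_per_type), rna_cells)
    atac_ann <- stats::setNames(rep(types, each = design$cells_per_type), atac_cells)

    # expression: NB per gene x type; copula for the correlated pair
    expr <- matrix(0, design$n_genes, n_cells,
                   dimnames = list(rownames(mm$mu), rna_cells))
    for (t in seq_along(types)) {
      cols <- which(rna_ann == types[t])
      mu_t <- mm$mu[, t]
      on <- which(mu_t > 0)
      expr[on, cols] <- stats::rnbinom(length(on) * length(cols),
                                       mu = rep(mu_t[on], length(cols)),
                                       size = design$nb_dispersion)
    }
    if (length(mm$pair)) {
      cp <- design$correlated_pair
      z1 <- stats::rnorm(n_cells)
      z2 <- cp$rho * z1 + sqrt(1 - cp$rho^2) * stats::rnorm(n_cells)
      expr[mm$pair[1], ] <- stats::qnbinom(stats::pnorm(z1), mu = cp$mean,
                                           size = cp$dispersion)
      expr[mm$pair[2], ] <- stats::qnbinom(stats::pnorm(z2), mu = cp$mean,
                                           size = cp$dispersion)
    }

    # ATAC: signal fragments at open elements + uniform background
    cfg <- pipeline_config()
    windows <- rbind(
      element_windows(ann$promoters, cfg)[, c("id", "chrom", "start", "end")],
      element_windows(ann$enhancers, cfg)[, c("id", "chrom", "start", "end")])
    elem_gene <- c(vapply(ann$promoters$gene_ids, `[`, "", 1),
                   vapply(ann$enhancers$gene_ids, `[`, "", 1))
    open_elements <- lapply(types, function(t)
      windows$id[elem_gene %in% rownames(mm$mu)[mm$mu[, t] > 0]])
    names(open_elements) <- types

    frag_chunks <- vector("list", design$n_cell_types + 1L)
    for (t in seq_along(types)) {
      open_idx <- which(windows$id %in% open_elements[[types[t]]])
      cells_t <- atac_cells[atac_ann == types[t]]
      if (length(open_idx) && design$atac_signal_fragments > 0) {
        k <- stats::rpois(length(open_idx) * length(cells_t),
                          design$atac_signal_fragments)
        ei <- rep(rep(open_idx, length(cells_t)), k)
        ci <- rep(rep(cells_t, each = length(open_idx)), k)
        ws <- windows$start[ei]
        we <- windows$end[ei]
        st <- ws + floor(stats::runif(length(ei)) * pmax(we - ws - 1L, 1L))
        frag_chunks[[t]] <- data.frame(
          chrom = windows$chrom[ei], start = st,
          end = st + design$fragment_length, barcode = ci,
          count = 1L, stringsAsFactors = FALSE)
      }
    }
    genome_kb <- sum(ann$chrom_len) / 1000
    lam <- design$atac_noise_rate * genome_kb
    if (lam > 0) {
      nbg <- stats::rpois(n_cells, lam)
      ci <- rep(atac_cells, nbg)
      chr <- sample(names(ann$chrom_len), length(ci), replace = TRUE,
                    prob = ann$chrom_len / sum(ann$chrom_len))
      st <- floor(stats::runif(length(ci)) *
                    (ann$chrom_len[chr] - design$fragment_length))
      frag_chunks[[design$n_cell_types + 1L]] <- data.frame(
        chrom = chr, start = as.integer(st),
        end = as.integer(st) + design$fragment_length, barcode = ci,
        count = 1L, stringsAsFactors = FALSE)
    }
    chunks <- frag_chunks[!vapply(frag_chunks, is.null, TRUE)]
    if (!length(chunks)) {
      frags <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), barcode = character(0),
                          count = integer(0))
    } else {
      dt <- data.table::rbindlist(chunks)
      data.table::setorder(dt, chrom, start, barcode)
      frags <- as.data.frame(dt)
    }
    attr(frags, "shifted") <- FALSE
    attr(frags, "malformed") <- 0L

    structure(list(
      expression = as_dgc(Matrix::Matrix(expr, sparse = TRUE)),
      fragments = frags,
      promoters = ann$promoters,
      enhancers = ann$enhancers,
      blacklist = ann$blacklist,
      rna_annotation = rna_ann,
      atac_annotation = atac_ann,
      truth = list(design = design, means = mm$mu,
                   marker_sets = lapply(types, function(t)
                     list(positive = mm$positive[[t]], negative = mm$negative[[t]])) |>
                     stats::setNames(types),
                   correlated_pair = mm$pair,
                   open_elements = open_elements)
    ), class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits every file in the formats the package readers consume:
#' `counts.mtx` (+ `genes.tsv`/`barcodes.tsv`), `fragments.tsv.gz`,
#' `promoters.bed`, `enhancers.bed`, `links.tsv`, `element_gc.tsv`,
#' `blacklist.bed`, `rna_annotation.tsv`, `atac_annotation.tsv`,
#' `markers.tsv` and `truth.json` (marker sets, open elements, design).
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expression, file.path(dir, "counts.mtx"))
  write_fragments(sim$fragments, file.path(dir, "fragments.tsv.gz"))
  write_bed_elements(sim$promoters, file.path(dir, "promoters.bed"))
  write_bed_elements(sim$enhancers, file.path(dir, "enhancers.bed"))
  data.table::fwrite(element_gene_pairs(sim$enhancers),
                     file.path(dir, "links.tsv"), sep = "\t", col.names = FALSE)
  gc_tab <- rbind(data.frame(id = sim$promoters$id, gc = sim$promoters$gc_fraction),
                  data.frame(id = sim$enhancers$id, gc = sim$enhancers$gc_fraction))
  data.table::fwrite(gc_tab, file.path(dir, "element_gc.tsv"), sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(sim$blacklist, file.path(dir, "blacklist.bed"), sep = "\t",
                     col.names = FALSE)
  write_cell_annotation(sim$rna_annotation, file.path(dir, "rna_annotation.tsv"))
  write_cell_annotation(sim$atac_annotation, file.path(dir, "atac_annotation.tsv"))
  write_markers(sim$truth$marker_sets, file.path(dir, "markers.tsv"))
  jsonlite::write_json(list(design = sim$truth$design[names(sim$truth$design) != "correlated_pair"],
                            marker_sets = sim$truth$marker_sets,
                            correlated_pair = sim$truth$correlated_pair,
                            open_elements = sim$truth$open_elements),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Inject simulated dropouts by Latin-hypercube rank sampling
#'
#' Within each cell type, exactly `round(rate * nnz_type)` non-zero entries
#' are set to zero — equal proportion for all cell types. To spread dropouts
#' over the expression range, the type's non-zero entries are sorted by
#' value rank, partitioned into `strata` equal-rank strata, and each
#' stratum's quota (the target split as evenly as possible, within one of
#' `target/strata`) is sampled uniformly without replacement. Only
#' previously non-zero entries are ever zeroed.
#'
#' @param m Genes-by-cells count matrix.
#' @param rate Dropout rate in \[0, 1).
#' @param annotation Named character vector: cell -> type (all cells).
#' @param seed Integer seed.
#' @param strata Number of rank strata (default 10).
#' @return List with `matrix` (same class/shape, masked entries zeroed) and
#'   `mask`: data.frame of `gene`, `cell`, `value` (the original values).
#' @export
inject_dropouts <- function(m, rate, annotation, seed = 1L, strata = 10L) {
  assert_that(rate >= 0 && rate < 1, "dropout rate must be in [0, 1)")
  m <- as_dgc(m)
  validate_annotation(annotation)
  cells <- colnames(m)
  assert_that(all(cells %in% names(annotation)), "every cell must be annotated")
  if (rate == 0) {
    return(list(matrix = m,
                mask = data.frame(gene = character(0), cell = character(0),
                                  value = numeric(0))))
  }
  trip <- sparse_triplets(m)
  labels <- unname(annotation[cells])
  type_of_entry <- labels[trip$j]

  withr::with_seed(seed, {
    masked <- lapply(unique(labels), function(t) {
      idx <- which(type_of_entry == t)
      target <- round(rate * length(idx))
      if (target == 0) return(integer(0))
      s_eff <- max(1L, min(as.integer(strata), length(idx)))
      ord <- idx[order(trip$x[idx], stats::runif(length(idx)))]  # seeded tie-break
      stratum <- split(ord, cut(seq_along(ord), s_eff, labels = FALSE))
      quota <- rep(target %/% s_eff, s_eff)
      extra <- target %% s_eff
      if (extra > 0) {
        bump <- sample.int(s_eff, extra)
        quota[bump] <- quota[bump] + 1L
      }
      # cap quotas at stratum size, reassigning leftovers where capacity remains
      sizes <- lengths(stratum)
      over <- pmax(quota - sizes, 0L)
      quota <- pmin(quota, sizes)
      leftover <- sum(over)
      while (leftover > 0) {
        room <- which(quota < sizes)
        take <- room[seq_len(min(length(room), leftover))]
        quota[take] <- quota[take] + 1L
        leftover <- leftover - length(take)
      }
      unlist(lapply(seq_len(s_eff), function(s) {
        if (quota[s] == 0) integer(0)
        else stratum[[s]][sample.int(sizes[s], quota[s])]
      }), use.names = FALSE)
    })
  })
  masked <- unlist(masked, use.names = FALSE)
  mask <- data.frame(gene = rownames(m)[trip$i[masked]],
                     cell = cells[trip$j[masked]],
                     value = trip$x[masked], stringsAsFactors = FALSE)
  keep <- setdiff(seq_along(trip$x), masked)
  out <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                              x = trip$x[keep], dims = dim(m),
                              dimnames = dimnames(m))
  list(matrix = as_dgc(out), mask = mask)
}

#' Restore masked dropout entries
#'
#' Exactly inverts [inject_dropouts()]: writing the mask's original values
#' back reproduces the input matrix.
#'
#' @param m Matrix with injected dropouts.
#' @param mask Mask data.frame from [inject_dropouts()].
#' @return Restored matrix.
#' @export
restore_dropouts <- function(m, mask) {
  m <- as_dgc(m)
  if (!nrow(mask)) return(m)
  trip <- sparse_triplets(m)
  out <- Matrix::sparseMatrix(
    i = c(trip$i, match(mask$gene, rownames(m))),
    j = c(trip$j, match(mask$cell, colnames(m))),
    x = c(trip$x, mask$value),
    dims = dim(m), dimnames = dimnames(m))
  as_dgc(out)
}

#' Per-type pseudo-bulk profile
#'
#' Mean expression per gene per cell type; the synthetic stand-in for a
#' matched bulk RNA-seq profile in [bulk_test()].
#'
#' @param m Genes-by-cells matrix.
#' @param annotation Named character vector: cell -> type.
#' @return Genes-by-types matrix of means.
#' @export
pseudo_bulk <- function(m, annotation) {
  validate_annotation(annotation)
  labels <- unname(annotation[colnames(m)])
  types <- unique(labels)
  out <- vapply(types, function(t)
    Matrix::rowSums(m[, labels == t, drop = FALSE]) / sum(labels == t),
    numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), types)
  out
}
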