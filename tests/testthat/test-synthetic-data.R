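test_that("generation is deterministic in the seed and validates the design", {
  d <- tiny_design(seed = 7)
  s1 <- simulate_dataset(d)
  s2 <- simulate_dataset(d)
  expect_identical(as.matrix(s1$expression), as.matrix(s2$expression))
  expect_identical(s1$fragments, s2$fragments)
  s3 <- simulate_dataset(tiny_design(seed = 8))
  expect_false(identical(s1$fragments, s3$fragments))

  expect_error(synthetic_design(n_genes = 10, n_cell_types = 3,
                                markers_per_type = 5),
               "exceeds n_genes")
  # no signal, no noise -> no fragments
  s0 <- simulate_dataset(tiny_design(atac_signal_fragments = 0,
                                     atac_noise_rate = 0))
  expect_identical(nrow(s0$fragments), 0L)
})

test_that("marker structure and NB means match the design", {
  d <- synthetic_design(n_cell_types = 3, cells_per_type = 200, n_genes = 300,
                        genes_per_chrom = 150, seed = 5)
  sim <- simulate_dataset(d)
  expect_identical(dim(sim$expression), c(300L, 600L))
  mu <- sim$truth$means
  for (t in names(sim$truth$marker_sets)) {
    pos <- sim$truth$marker_sets[[t]]$positive
    neg <- sim$truth$marker_sets[[t]]$negative
    expect_true(all(mu[pos, t] > 0))
    expect_true(all(mu[pos, setdiff(colnames(mu), t)] == 0))
    expect_true(all(mu[neg, t] == 0))
    # sample mean of a positive marker within 3 SE of the NB mean
    cells_t <- names(sim$rna_annotation)[sim$rna_annotation == t]
    for (g in pos[1:3]) {
      x <- as.numeric(sim$expression[g, cells_t])
      se <- sqrt((d$marker_mean + d$marker_mean^2 / d$nb_dispersion) /
                   length(cells_t))
      expect_lt(abs(mean(x) - d$marker_mean), 3 * se)
    }
  }
  # open elements cover all elements of expressed genes, per type
  for (t in colnames(mu)) {
    expressed <- rownames(mu)[mu[, t] > 0]
    expect_true(all(paste0("prom_", expressed) %in%
                      sim$truth$open_elements[[t]]))
  }
})

test_that("written datasets round-trip through the readers", {
  sim <- simulate_dataset(tiny_design(seed = 3))
  dir <- tempfile()
  write_dataset(sim, dir)
  m <- read_expression(file.path(dir, "counts.mtx"))
  expect_equal(as.matrix(m), as.matrix(sim$expression))
  fr <- read_fragments(file.path(dir, "fragments.tsv.gz"))
  expect_identical(nrow(fr), nrow(sim$fragments))
  ann <- read_cell_annotation(file.path(dir, "rna_annotation.tsv"))
  expect_identical(ann, sim$rna_annotation)
  mk <- read_markers(file.path(dir, "markers.tsv"))
  expect_identical(sort(mk$type1$positive),
                   sort(sim$truth$marker_sets$type1$positive))
  prom <- read_bed_elements(file.path(dir, "promoters.bed"), "promoter",
                            gc = file.path(dir, "element_gc.tsv"))
  expect_equal(prom$start, sim$promoters$start)
  expect_equal(prom$gc_fraction, sim$promoters$gc_fraction)
})

test_that("dropout injection zeroes exactly the per-type quota of non-zeros", {
  sim <- simulate_dataset(tiny_design(seed = 2))
  m <- sim$expression
  ann <- sim$rna_annotation
  for (rate in c(0.25, 0.5, 0.75, 0.95)) {
    dd <- inject_dropouts(m, rate, ann, seed = 10)
    for (t in unique(ann)) {
      cells_t <- names(ann)[ann == t]
      nnz_t <- sum(m[, cells_t] > 0)
      expect_identical(sum(dd$mask$cell %in% cells_t),
                       as.integer(round(rate * nnz_t)))
    }
    # never creates a new non-zero; conservation of positions
    expect_true(all(as.matrix(dd$matrix)[as.matrix(m) == 0] == 0))
    orig <- which(as.matrix(m) > 0)
    surv <- which(as.matrix(dd$matrix) > 0)
    masked <- cbind(match(dd$mask$gene, rownames(m)),
                    match(dd$mask$cell, colnames(m)))
    masked_lin <- (masked[, 2] - 1) * nrow(m) + masked[, 1]
    expect_setequal(c(surv, masked_lin), orig)
    # restore is the exact inverse
    expect_identical(as.matrix(restore_dropouts(dd$matrix, dd$mask)),
                     as.matrix(m))
  }
  dd0 <- inject_dropouts(m, 0, ann, seed = 1)
  expect_identical(as.matrix(dd0$matrix), as.matrix(m))
  expect_identical(nrow(dd0$mask), 0L)
  expect_error(inject_dropouts(m, 1, ann), "rate")
})

test_that("dropouts span the expression range, not just one tail", {
  sim <- simulate_dataset(tiny_design(seed = 4))
  m <- sim$expression
  ann <- sim$rna_annotation
  dd <- inject_dropouts(m, 0.5, ann, seed = 20, strata = 10L)
  for (t in unique(ann)) {
    cells_t <- names(ann)[ann == t]
    sub <- as.matrix(m[, cells_t])
    vals <- sub[sub > 0]
    masked_vals <- dd$mask$value[dd$mask$cell %in% cells_t]
    expect_true(all(masked_vals > 0))
    # the stratified sampler must hit both the low and the high end
    expect_lte(min(masked_vals), quantile(vals, 0.2))
    expect_gte(max(masked_vals), quantile(vals, 0.8))
  }
})

test_that("the exact per-stratum quota holds on a tie-free matrix", {
  withr::with_seed(6, {
    vals <- sample(seq(1, 500, by = 0.25), 400)
    m <- Matrix::Matrix(matrix(vals, 40, 10), sparse = TRUE)
  })
  dimnames(m) <- list(paste0("g", 1:40), paste0("c", 1:10))
  ann <- setNames(rep("t1", 10), colnames(m))
  S <- 10L
  dd <- inject_dropouts(m, 0.3, ann, seed = 3, strata = S)
  target <- round(0.3 * 400)
  ord <- sort(vals)
  stratum_bounds <- split(ord, rep(1:S, each = 40))
  lost <- vapply(1:S, function(s)
    sum(dd$mask$value %in% stratum_bounds[[s]]), 0L)
  expect_true(all(lost >= floor(target / S)))
  expect_true(all(lost <= ceiling(target / S)))
})
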