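test_that("marker test arithmetic matches hand counts", {
  truth <- rbind(pos1 = c(4, 0, 7, 2), neg1 = c(0, 0, 3, 0))
  imput <- rbind(pos1 = c(4, 0.6, 0, 2), neg1 = c(0.5, 0, 3, 0))
  colnames(truth) <- colnames(imput) <- paste0("c", 1:4)
  ann <- setNames(rep("A", 4), colnames(truth))
  mk <- list(A = list(positive = "pos1", negative = "neg1"))
  res <- marker_test(imput, truth, mk, ann)
  # positives: truth non-zero at c1, c3, c4; imputed non-zero at c1, c4
  expect_identical(c(res$tp, res$fn), c(2L, 1L))
  # negatives: truth zero at c1, c2, c4; imputed non-zero at c1
  expect_identical(c(res$fp, res$tn), c(1L, 2L))
  expect_equal(res$tpr, 2 / 3)
  expect_equal(res$fpr, 1 / 3)

  # empty classes give NA, never 0
  mk2 <- list(A = list(positive = character(0), negative = "neg1"))
  res2 <- marker_test(imput, truth, mk2, ann)
  expect_true(is.na(res2$tpr))
  expect_false(is.na(res2$fpr))
  # an indiscriminate adder lights every negative: fpr = 1
  res3 <- marker_test(imput + 1, truth, mk, ann)
  expect_equal(res3$fpr, 1)
  expect_equal(res3$tpr, 1)
  # markers absent from the matrix are skipped with a message
  mk3 <- list(A = list(positive = c("pos1", "ghost"), negative = "neg1"))
  expect_message(res4 <- marker_test(imput, truth, mk3, ann), "absent")
  expect_identical(res4$tp, res$tp)
})

test_that("bulk test derives classes from the top fraction and bulk zeros", {
  genes <- paste0("g", 1:10)
  truth <- matrix(5, 10, 2, dimnames = list(genes, c("c1", "c2")))
  truth["g10", ] <- 0
  bulk <- matrix(c(10:2, 0), 10, 1, dimnames = list(genes, "A"))
  ann <- setNames(c("A", "A"), c("c1", "c2"))
  imput <- truth
  imput["g1", "c1"] <- 0        # miss one positive-class truthy entry
  imput["g10", "c2"] <- 0.4     # light one bulk-zero entry
  res <- bulk_test(imput, truth, bulk, ann, top_fraction = 0.2)
  # positive class: g1, g2 (top 20%); 4 truthy entries, 3 recovered
  expect_equal(res$tpr, 3 / 4)
  # negative class: g10 (bulk zero); both truth zero, one imputed non-zero
  expect_equal(res$fpr, 1 / 2)
  expect_error(bulk_test(imput, truth, bulk, ann, top_fraction = 0),
               "top_fraction")
})

test_that("stratified error reproduces closed-form F1 cases", {
  genes <- paste0("g", 1:4); cells <- paste0("c", 1:4)
  truth <- matrix(0, 4, 4, dimnames = list(genes, cells))
  truth[1, ] <- c(1, 2, 3, 4)
  dropped <- truth
  dropped[1, 1:2] <- 0
  mask <- data.frame(gene = "g1", cell = c("c1", "c2"), value = c(1, 2))

  # perfect recovery, no false positives: error 0 everywhere observed
  perfect <- truth
  res <- stratified_error(perfect, truth, mask)
  expect_equal(res$overall, 0)
  expect_true(all(res$per_stratum$error[res$per_stratum$n > 0] == 0))

  # nothing imputed: recall 0 -> F1 0 -> error 1
  res0 <- stratified_error(dropped, truth, mask)
  expect_equal(res0$overall, 1)

  # recall 1/2 and precision 1/2 -> F1 1/2 -> error 1/2:
  # one of two masked entries recovered, one true zero lit
  half <- dropped
  half["g1", "c1"] <- 0.7       # recover the stratum-1 masked entry
  half["g2", "c1"] <- 0.7       # one false positive on a true zero
  res5 <- stratified_error(half, truth, mask, breaks = numeric(0))
  expect_equal(res5$per_stratum$recall[1], 1 / 2)
  expect_equal(res5$per_stratum$precision[1], 1 / 2)
  expect_equal(res5$overall, 1 / 2)

  expect_error(stratified_error(truth, truth, mask[0, ]), "empty")
})

test_that("stratified error anchors true-zero false positives in stratum 1", {
  genes <- paste0("g", 1:3); cells <- paste0("c", 1:8)
  truth <- matrix(0, 3, 8, dimnames = list(genes, cells))
  truth[1, ] <- 1:8
  mask <- data.frame(gene = "g1", cell = cells, value = 1:8)
  imput <- truth                 # all masked entries recovered
  imput["g2", 1] <- 0.5          # plus one true-zero false positive
  res <- stratified_error(imput, truth, mask, breaks = c(2.5, 4.5, 6.5))
  per <- res$per_stratum
  expect_identical(nrow(per), 4L)
  expect_true(all(per$recall == 1))
  expect_lt(per$precision[1], 1)        # FP charged to the lowest stratum
  expect_true(all(per$precision[2:4] == 1))
  expect_true(per$error[1] > 0 && all(per$error[2:4] == 0))
})

test_that("imputation error degrades monotonically from imperfect recovery", {
  # property over seeds: recovering fewer masked entries never lowers the error
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 50
      truth <- matrix(rpois(n * 4, 4) + 1, n, 4,
                      dimnames = list(paste0("g", 1:n), paste0("c", 1:4)))
      mask_idx <- sample(n * 4, 60)
      mask <- data.frame(
        gene = rownames(truth)[(mask_idx - 1) %% n + 1],
        cell = colnames(truth)[(mask_idx - 1) %/% n + 1],
        value = truth[mask_idx])
      dropped <- truth; dropped[mask_idx] <- 0
      recov_frac <- c(1, 0.6, 0.2)
      errs <- vapply(recov_frac, function(fr) {
        imp <- dropped
        rec <- mask_idx[seq_len(round(fr * length(mask_idx)))]
        imp[rec] <- 0.9
        stratified_error(imp, truth, mask)$overall
      }, 0)
      expect_true(all(diff(errs) >= 0))
    })
  }
})

test_that("correlation preservation recovers exact closed-form correlations", {
  withr::with_seed(2, x <- rnorm(40, 10))
  M1 <- rbind(a = x, b = 2 * x)              # r = 1 exactly
  M2 <- rbind(a = x, b = max(x) + 1 - x)     # r = -1 exactly
  colnames(M1) <- colnames(M2) <- paste0("c", 1:40)
  pairs <- data.frame(gene1 = "a", gene2 = "b")
  res <- correlation_preservation(list(m1 = M1, m2 = M2), pairs,
                                  reference_r = 0.5, cells = "all")
  expect_equal(res$r[res$matrix == "m1"], 1)
  expect_equal(res$r[res$matrix == "m2"], -1)
  expect_equal(res$abs_dev[res$matrix == "m1"], 0.5)
  # zero-variance gene yields NA
  M3 <- rbind(a = rep(5, 40), b = x); colnames(M3) <- colnames(M1)
  res3 <- correlation_preservation(list(m3 = M3), pairs, 0.5, cells = "all")
  expect_true(is.na(res3$r))
  # default convention drops cells where both genes are zero
  M4 <- rbind(a = c(0, 0, 1, 2, 3), b = c(0, 0, 2, 4, 6))
  colnames(M4) <- paste0("c", 1:5)
  res4 <- correlation_preservation(list(m4 = M4), pairs, 1)
  expect_identical(res4$n_cells, 3L)
  expect_equal(res4$r, 1)
  # missing gene reported as NA row, input length checked
  res5 <- correlation_preservation(list(m4 = M4[1, , drop = FALSE]), pairs, 1)
  expect_true(is.na(res5$r))
  expect_error(correlation_preservation(list(m = M4), pairs, c(1, 2)),
               "one value per gene pair")
})

test_that("run_benchmark scores every requested rate on a tiny dataset", {
  sim <- simulate_dataset(tiny_design(seed = 6))
  bm <- run_benchmark(sim, rates = c(0.25, 0.5), seed = 3)
  expect_s3_class(bm, "benchmark_result")
  expect_named(bm, c("rate_0.25", "rate_0.5"))
  for (r in bm) {
    expect_true(r$marker$tpr >= 0 && r$marker$tpr <= 1)
    expect_true(r$bulk$fpr >= 0 && r$bulk$fpr <= 1)
    expect_true(r$error$overall >= 0 && r$error$overall <= 1)
    expect_identical(sort(unique(r$correlation$matrix)),
                     sort(c("raw", "dropout", "imputed")))
  }
  expect_error(run_benchmark(sim, rates = c(0.5, 1)), "rates")
})
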