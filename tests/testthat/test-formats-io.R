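test_that("dense TSV expression matrices parse with the expected sparsity", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "g1\t0\t0", "g2\t1\t2", "g3\t5\t0"), tsv)
  m <- read_expression(tsv)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(length(m@x), 3L)
  expect_equal(as.numeric(m["g2", ]), c(1, 2))
})

test_that("expression readers reject malformed and degenerate input", {
  dir <- tempfile(); dir.create(dir)
  mtx <- file.path(dir, "bad.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "3 2 10",
               "1 1 1", "2 1 5", "3 2 2"), mtx)
  writeLines(paste0("g", 1:3), file.path(dir, "genes.tsv"))
  writeLines(paste0("c", 1:2), file.path(dir, "barcodes.tsv"))
  expect_error(read_expression(mtx), "malformed MatrixMarket")

  empty <- file.path(dir, "empty.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "3 0 0"), empty)
  expect_error(read_expression(empty), "no cells")

  ok <- file.path(dir, "ok.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "3 2 2",
               "1 1 1", "3 2 -4"), ok)
  expect_error(read_expression(ok), "negative entry")

  short <- file.path(dir, "short.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general", "4 2 1",
               "1 1 1"), short)
  expect_error(read_expression(short), "dimension mismatch")
})

test_that("expression write/read round-trips exactly for both formats", {
  m <- rand_sparse(5, 5, seed = 7)
  # fractional (imputed-like) values survive the round trip
  m@x <- m@x + 0.37
  dir <- tempfile(); dir.create(dir)
  p1 <- file.path(dir, "m.mtx")
  write_expression(m, p1)
  expect_equal(as.matrix(read_expression(p1)), as.matrix(m), tolerance = 1e-12)
  p2 <- file.path(dir, "m.tsv")
  write_expression(m, p2)
  expect_equal(as.matrix(read_expression(p2)), as.matrix(m), tolerance = 1e-12)
  zero_gene <- m[integer(0), , drop = FALSE]
  expect_error(write_expression(zero_gene, p1), "no genes")
})

test_that("fragment files parse, skip start>=end records, and round-trip gzip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t250\tAAAC", "chr1\t300\t300\tAAAC",
               "chr2\t5\t60\tGGGT\t3"), f)
  expect_warning(fr <- read_fragments(f), "start >= end")
  expect_identical(nrow(fr), 2L)
  expect_identical(attr(fr, "malformed"), 1L)
  expect_equal(fr$start, c(100L, 5L))
  expect_equal(fr$count[2], 3L)
  expect_false(attr(fr, "shifted"))

  # same content interpreted as MAPQ
  expect_warning(fr_mq <- read_fragments(f, fifth_column = "mapq"))
  expect_identical(fr_mq$mapq[2], 3L)

  gz <- tempfile(fileext = ".tsv.gz")
  write_fragments(fr, gz)
  fr2 <- read_fragments(gz)
  expect_equal(fr2[, c("chrom", "start", "end", "barcode")],
               fr[, c("chrom", "start", "end", "barcode")])

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t250\tAAAC", "chr1\tnotanumber\t9\tAAAC"), bad)
  expect_error(read_fragments(bad), "unparseable start .* line 2")
})

test_that("BED element reading enforces promoter strand and resolves links", {
  prom <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t9999\t10000\tGENE1\t0\t+",
               "chr1\t20000\t20001\tGENE2\t0\t-"), prom)
  pe <- read_bed_elements(prom, "promoter")
  expect_identical(pe$kind, rep("promoter", 2))
  expect_identical(unlist(pe$gene_ids), c("GENE1", "GENE2"))

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t9999\t10000\tGENE1\t0\t.", bad)
  expect_error(read_bed_elements(bad, "promoter"), "strand")

  enh <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1400\tE1", "chr1\t5000\t5200\tE2"), enh)
  links <- tempfile(fileext = ".tsv")
  writeLines(c("E1\tGENE1", "E1\tGENE2", "EX\tGENE3"), links)
  expect_warning(ee <- read_bed_elements(enh, "enhancer", links = links),
                 "unknown enhancer")
  expect_identical(ee$gene_ids[[which(ee$id == "E1")]], c("GENE1", "GENE2"))
  expect_false(ee$linked[ee$id == "E2"])
  expect_length(ee$gene_ids[[which(ee$id == "E2")]], 0)

  gc_tab <- data.frame(id = c("E1", "E2"), gc = c(0.41, 0.62))
  ee2 <- read_bed_elements(enh, "enhancer", links = links, gc = gc_tab) |>
    suppressWarnings()
  expect_equal(ee2$gc_fraction, c(0.41, 0.62))
})

test_that("BED coordinates round-trip unchanged", {
  els <- make_elements("chr3", c(100, 900), c(400, 1800), id = c("A", "B"))
  p <- tempfile(fileext = ".bed")
  write_bed_elements(els, p)
  back <- read_bed_elements(p, "enhancer")
  expect_equal(back$start, els$start)
  expect_equal(back$end, els$end)
  expect_equal(back$id, els$id)
})

test_that("annotations and marker tables round-trip", {
  ann <- c(AAA = "HSC", BBB = "CMP", CCC = "HSC")
  p <- tempfile(fileext = ".tsv")
  write_cell_annotation(ann, p)
  expect_identical(read_cell_annotation(p), ann)
  expect_error(write_cell_annotation(c(A = "x", A = "y"), p), "duplicated")

  mk <- list(HSC = list(positive = c("CD34", "CD59"), negative = "FLT3"),
             CMP = list(positive = "FLT3", negative = "PTPRC"))
  pm <- tempfile(fileext = ".tsv")
  write_markers(mk, pm)
  expect_equal(read_markers(pm), mk)
})
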