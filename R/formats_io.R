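# Readers and writers for every external format the pipeline touches.
# All genomic coordinates are BED-native 0-based half-open. The TSS of a "+"
# gene is `start`; of a "-" gene it is `end - 1`.

#' Read a gene-by-cell expression count matrix
#'
#' Supports MatrixMarket coordinate format with `genes.tsv`/`barcodes.tsv`
#' sidecar files (10x triplet convention) and dense TSV (first column = gene
#' ids, header row = cell barcodes).
#'
#' @param path Path to the `.mtx` file or dense TSV.
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`. `"auto"` decides from the
#'   file extension.
#' @param genes,barcodes Optional explicit sidecar paths (MTX only). Defaults
#'   to `genes.tsv` and `barcodes.tsv` next to `path` (`features.tsv`
#'   accepted as a fallback).
#' @return A [Matrix::dgCMatrix-class] with genes as rownames and cell
#'   barcodes as colnames. All entries are non-negative.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv"),
                            genes = NULL, barcodes = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    as_mm_error <- function(c) stop2("malformed MatrixMarket file '", path,
                                     "': ", conditionMessage(c))
    # readMM only warns on truncated entry lists; treat that as fatal too
    m <- withCallingHandlers(
      tryCatch(Matrix::readMM(path), error = as_mm_error),
      warning = as_mm_error)
    assert_that(ncol(m) > 0, "no cells in expression matrix")
    assert_that(nrow(m) > 0, "no genes in expression matrix")
    dir <- dirname(path)
    if (is.null(genes)) {
      genes <- file.path(dir, "genes.tsv")
      if (!file.exists(genes)) genes <- file.path(dir, "features.tsv")
    }
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    assert_that(file.exists(genes), paste0("gene sidecar not found: ", genes))
    assert_that(file.exists(barcodes), paste0("barcode sidecar not found: ", barcodes))
    gid <- data.table::fread(genes, header = FALSE, sep = "\t")[[1]]
    bc <- data.table::fread(barcodes, header = FALSE, sep = "\t")[[1]]
    assert_that(nrow(m) == length(gid),
                sprintf("dimension mismatch: matrix has %d rows but %d gene ids",
                        nrow(m), length(gid)))
    assert_that(ncol(m) == length(bc),
                sprintf("dimension mismatch: matrix has %d columns but %d barcodes",
                        ncol(m), length(bc)))
    dimnames(m) <- list(gid, bc)
    m <- as_dgc(m)
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    assert_that(ncol(dt) >= 2, "dense TSV must have a gene-id column plus >=1 cell")
    gid <- as.character(dt[[1]])
    vals <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))) & !is.na(vals))
      stop2("non-numeric entry in dense TSV near data line ",
            if (length(bad)) ((bad[1] - 1) %% nrow(vals)) + 2 else "?")
    }
    rownames(vals) <- gid
    m <- as_dgc(Matrix::Matrix(vals, sparse = TRUE))
  }
  validate_expression(m)
}

validate_expression <- function(m) {
  assert_that(ncol(m) > 0, "no cells in expression matrix")
  assert_that(nrow(m) > 0, "no genes in expression matrix")
  assert_that(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
              "duplicate or missing gene ids")
  assert_that(!is.null(colnames(m)) && !anyDuplicated(colnames(m)),
              "duplicate or missing cell barcodes")
  if (any(m@x < 0)) {
    k <- which(m@x < 0)[1]
    stop2("negative entry in expression matrix (value ", m@x[k], ")")
  }
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: MTX plus `genes.tsv`/`barcodes.tsv`
#' sidecars, or dense TSV. Round-trips exactly up to float formatting.
#'
#' @param m Gene-by-cell matrix with dimnames.
#' @param path Output path (`.mtx` or `.tsv`).
#' @param format `"auto"`, `"mtx"` or `"tsv"`.
#' @export
write_expression <- function(m, path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  m <- validate_expression(as_dgc(m))
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    Matrix::writeMM(m, path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    dt <- data.table::data.table(gene = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(as.matrix(m)))
    data.table::setnames(dt, c("gene", colnames(m)))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read an ATAC fragments file
#'
#' Tab-separated with at least four columns (chrom, start, end, barcode) and
#' an optional fifth column whose meaning is configurable, since both dialects
#' exist in the wild: a duplicate count (10x convention, the default) or a
#' mapping quality. Gzip input is handled transparently. Records with
#' `start >= end` are skipped with a warning and tallied in the `"malformed"`
#' attribute.
#'
#' @param path Fragments TSV (optionally gzipped).
#' @param shifted Logical: have Tn5 offsets (+4/-5) already been applied
#'   (10x-style fragment files)? Recorded and honoured by [tn5_shift()].
#' @param fifth_column Interpretation of the optional 5th column: `"count"`
#'   (default) or `"mapq"`. With `"count"` the MAPQ filter is inapplicable
#'   downstream.
#' @return A data.frame with columns `chrom`, `start`, `end`, `barcode` and
#'   (if present) `count` or `mapq`; attributes `shifted` and `malformed`.
#' @export
read_fragments <- function(path, shifted = FALSE,
                           fifth_column = c("count", "mapq")) {
  fifth_column <- match.arg(fifth_column)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (grepl("\\.gz$", path)) {
    # decompress through a base connection: no optional fread helpers needed
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    lines <- readLines(con)
    assert_that(length(lines) > 0, "fragments file is empty")
    dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                            fill = TRUE, colClasses = list(character = 1))
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = 1))
  }
  assert_that(nrow(dt) > 0, "fragments file is empty")
  assert_that(ncol(dt) >= 4,
              "fragments file must have >=4 columns (chrom, start, end, barcode)")
  names(dt)[1:4] <- c("chrom", "start", "end", "barcode")
  has5 <- ncol(dt) >= 5
  if (has5) names(dt)[5] <- fifth_column
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop2("unparseable ", col, " field at line ", bad[1], " of ", path)
    }
    data.table::set(dt, j = col, value = v)
  }
  assert_that(all(nzchar(dt$barcode) & !is.na(dt$barcode)),
              "fragments file contains empty barcodes")
  assert_that(all(dt$start >= 0), "fragments file contains negative coordinates")
  malformed <- which(dt$start >= dt$end)
  if (length(malformed)) {
    warning(length(malformed), " fragment record(s) with start >= end skipped",
            call. = FALSE)
    dt <- dt[-malformed, ]
  }
  out <- as.data.frame(dt)[, c("chrom", "start", "end", "barcode",
                               if (has5) fifth_column)]
  attr(out, "shifted") <- isTRUE(shifted)
  attr(out, "malformed") <- length(malformed)
  out
}

#' Write an ATAC fragments file
#'
#' @param frags Fragments data.frame as returned by [read_fragments()].
#' @param path Output TSV; gzipped if the path ends in `.gz`.
#' @export
write_fragments <- function(frags, path) {
  data.table::fwrite(as.data.frame(frags), path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

new_regulatory_elements <- function(df) {
  validate_intervals(df, "regulatory element")
  assert_that(!anyDuplicated(df$id), "duplicate regulatory element ids")
  assert_that(all(df$kind %in% c("promoter", "enhancer")),
              "element kind must be promoter or enhancer")
  prom <- df$kind == "promoter"
  assert_that(all(lengths(df$gene_ids[prom]) == 1L),
              "promoter elements must link exactly one gene")
  ok <- is.na(df$gc_fraction) | (df$gc_fraction >= 0 & df$gc_fraction <= 1)
  assert_that(all(ok), "gc_fraction must be in [0,1] or NA")
  class(df) <- c("regulatory_elements", "data.frame")
  df
}

#' Read regulatory elements from BED
#'
#' Promoter TSS records require BED6 (the window is strand-dependent, so a
#' missing or "." strand is an error); the BED name field is the gene id.
#' Enhancers are BED3+ (name field = enhancer id, auto-generated when absent)
#' and may be linked to one or more genes through a two-column
#' enhancer-id/gene-id TSV. Enhancers without any link are retained but
#' flagged unlinked; they are excluded from gene-level aggregation.
#'
#' @param path BED file.
#' @param kind `"promoter"` or `"enhancer"`.
#' @param links Optional path (or data.frame) of enhancer-id/gene-id pairs.
#'   Links referencing unknown enhancer ids are dropped with a warning.
#' @param gc Optional GC fractions: a path to a two-column id/gc TSV, a
#'   data.frame, or a named numeric vector. Values in \[0,1\].
#' @return A `regulatory_elements` data.frame: columns `id`, `chrom`, `start`,
#'   `end`, `strand`, `kind`, `gc_fraction`, `linked`, plus a `gene_ids`
#'   list-column.
#' @export
read_bed_elements <- function(path, kind = c("promoter", "enhancer"),
                              links = NULL, gc = NULL) {
  kind <- match.arg(kind)
  assert_that(file.exists(path), paste0("file not found: ", path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  assert_that(ncol(dt) >= 3, "BED file must have >=3 columns")
  chrom <- as.character(dt[[1]])
  start <- as.integer(dt[[2]])
  end <- as.integer(dt[[3]])
  name <- if (ncol(dt) >= 4) as.character(dt[[4]]) else rep(NA_character_, nrow(dt))
  strand <- if (ncol(dt) >= 6) as.character(dt[[6]]) else rep(".", nrow(dt))

  if (kind == "promoter") {
    assert_that(ncol(dt) >= 6 && all(strand %in% c("+", "-")),
                "promoter records require BED6 with strand '+' or '-' (window is strand-dependent)")
    assert_that(all(!is.na(name) & nzchar(name)),
                "promoter records require a gene id in the BED name field")
    df <- data.frame(id = paste0("prom_", name), chrom = chrom, start = start,
                     end = end, strand = strand, kind = "promoter",
                     gc_fraction = NA_real_, linked = TRUE,
                     stringsAsFactors = FALSE)
    df$gene_ids <- as.list(name)
  } else {
    id <- ifelse(is.na(name) | !nzchar(name),
                 paste0("enh_", seq_len(nrow(dt))), name)
    df <- data.frame(id = id, chrom = chrom, start = start, end = end,
                     strand = ".", kind = "enhancer", gc_fraction = NA_real_,
                     linked = FALSE, stringsAsFactors = FALSE)
    df$gene_ids <- replicate(nrow(df), character(0), simplify = FALSE)
    if (!is.null(links)) {
      lk <- if (is.character(links)) {
        as.data.frame(data.table::fread(links, header = FALSE, sep = "\t"))
      } else as.data.frame(links)
      assert_that(ncol(lk) >= 2, "links must have two columns: enhancer id, gene id")
      names(lk)[1:2] <- c("element", "gene")
      unknown <- !(lk$element %in% df$id)
      if (any(unknown)) {
        warning(sum(unknown), " link(s) reference unknown enhancer ids; dropped",
                call. = FALSE)
        lk <- lk[!unknown, , drop = FALSE]
      }
      gl <- split(as.character(lk$gene), factor(lk$element, levels = df$id))
      df$gene_ids <- lapply(gl, unique)
      df$linked <- lengths(df$gene_ids) > 0
    }
  }
  if (!is.null(gc)) {
    gcv <- if (is.character(gc) && length(gc) == 1 && file.exists(gc)) {
      tab <- data.table::fread(gc, header = FALSE, sep = "\t")
      stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
    } else if (is.data.frame(gc)) {
      stats::setNames(as.numeric(gc[[2]]), as.character(gc[[1]]))
    } else gc
    df$gc_fraction <- unname(gcv[df$id])
  }
  new_regulatory_elements(df)
}

#' Write regulatory elements to BED
#'
#' Promoters are written as BED6 (name = gene id); enhancers as BED4.
#'
#' @param elements A `regulatory_elements` data.frame.
#' @param path Output BED path.
#' @export
write_bed_elements <- function(elements, path) {
  if (all(elements$kind == "promoter")) {
    dt <- data.frame(elements$chrom, elements$start, elements$end,
                     vapply(elements$gene_ids, `[`, "", 1),
                     0L, elements$strand)
  } else {
    dt <- data.frame(elements$chrom, elements$start, elements$end, elements$id)
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# element-id / gene-id pairs for linked elements only
element_gene_pairs <- function(elements) {
  n <- lengths(elements$gene_ids)
  data.frame(element = rep(elements$id, n),
             gene = unlist(elements$gene_ids, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read a cell annotation table
#'
#' Two-column TSV mapping barcode to cell-type label. A header row named
#' `barcode`/`label` is tolerated and skipped.
#'
#' @param path TSV path.
#' @return Named character vector: `names` are barcodes, values are labels.
#' @export
read_cell_annotation <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  assert_that(ncol(dt) >= 2, "annotation must have two columns: barcode, label")
  if (tolower(dt[[1]][1]) %in% c("barcode", "cell")) dt <- dt[-1, ]
  ann <- stats::setNames(as.character(dt[[2]]), as.character(dt[[1]]))
  validate_annotation(ann)
  ann
}

#' Write a cell annotation table
#' @param annotation Named character vector (barcode -> label).
#' @param path Output TSV path.
#' @export
write_cell_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  data.table::fwrite(data.frame(barcode = names(annotation),
                                label = unname(annotation)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a surface-marker table
#'
#' Three-column TSV: cell-type label, gene id, `positive`/`negative`. The
#' same gene may be positive for one type and negative for another.
#'
#' @param path TSV path.
#' @return Named list; per type a list with `positive` and `negative`
#'   character vectors of gene ids.
#' @export
read_markers <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t"))
  assert_that(ncol(dt) >= 3, "markers must have three columns: type, gene, class")
  names(dt)[1:3] <- c("type", "gene", "class")
  assert_that(all(dt$class %in% c("positive", "negative")),
              "marker class must be 'positive' or 'negative'")
  lapply(split(dt, factor(dt$type, levels = unique(dt$type))), function(d) {
    list(positive = d$gene[d$class == "positive"],
         negative = d$gene[d$class == "negative"])
  })
}

#' Write a surface-marker table
#' @param markers Named list as returned by [read_markers()].
#' @param path Output TSV path.
#' @export
write_markers <- function(markers, path) {
  rows <- do.call(rbind, lapply(names(markers), function(t) {
    rbind(data.frame(type = t, gene = markers[[t]]$positive, class = "positive"),
          data.frame(type = t, gene = markers[[t]]$negative, class = "negative"))
  }))
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file of blacklist regions
#' @param path BED3 path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_blacklist <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  assert_that(ncol(dt) >= 3, "blacklist BED must have >=3 columns")
  df <- data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  validate_intervals(df, "blacklist region")
  df
}
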