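# Shared fixture builders. Everything is generated in code; no binary files.

# a small but structurally complete design for fast tests
tiny_design <- function(seed = 1L, ...) {
  synthetic_design(n_cell_types = 3L, cells_per_type = 30L, n_genes = 120L,
                   markers_per_type = 8L, negative_markers_per_type = 8L,
                   genes_per_chrom = 60L, blacklist_width = 20000L,
                   seed = seed, ...)
}

make_frags <- function(chrom, start, end, barcode, mapq = NULL, count = NULL,
                       shifted = TRUE) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), barcode = barcode,
                   stringsAsFactors = FALSE)
  if (!is.null(mapq)) df$mapq <- as.integer(mapq)
  if (!is.null(count)) df$count <- as.integer(count)
  attr(df, "shifted") <- shifted
  attr(df, "malformed") <- 0L
  df
}

make_elements <- function(chrom, start, end, id = NULL, gene = NULL,
                          kind = "enhancer", strand = ".", gc = NA_real_) {
  n <- length(start)
  id <- id %||% paste0("el", seq_len(n))
  gene <- gene %||% paste0("g", seq_len(n))
  df <- data.frame(id = id, chrom = chrom, start = as.integer(start),
                   end = as.integer(end), strand = strand, kind = kind,
                   gc_fraction = gc, linked = TRUE, stringsAsFactors = FALSE)
  df$gene_ids <- as.list(gene)
  class(df) <- c("regulatory_elements", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent all-pairs overlap scan oracle for fragment counting
brute_count <- function(frags, elements, cells, mode = c("overlap", "insertion"),
                        mapq_min = 30L) {
  mode <- match.arg(mode)
  m <- matrix(0, nrow(elements), length(cells),
              dimnames = list(elements$id, cells))
  for (f in seq_len(nrow(frags))) {
    if (!is.null(frags$mapq) && !(frags$mapq[f] > mapq_min)) next
    b <- frags$barcode[f]
    if (!(b %in% cells)) next
    for (e in seq_len(nrow(elements))) {
      if (frags$chrom[f] != elements$chrom[e]) next
      if (mode == "overlap") {
        if (frags$start[f] < elements$end[e] && frags$end[f] > elements$start[e]) {
          m[e, b] <- m[e, b] + 1
        }
      } else {
        for (pos in c(frags$start[f], frags$end[f] - 1L)) {
          if (pos >= elements$start[e] && pos < elements$end[e]) {
            m[e, b] <- m[e, b] + 1
          }
        }
      }
    }
  }
  m
}

# independent classical quantile normalization (sort-and-average reference)
classical_qn <- function(X) {
  ref <- rowMeans(apply(X, 2, sort))
  out <- X
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

# sort-based median oracle
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) unname(s[(n + 1) / 2]) else unname((s[n / 2] + s[n / 2 + 1]) / 2)
}

rand_sparse <- function(nr, nc, density = 0.4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0, nr, nc, dimnames = list(paste0("g", seq_len(nr)),
                                           paste0("c", seq_len(nc))))
    nz <- round(density * nr * nc)
    idx <- sample(nr * nc, nz)
    m[idx] <- round(runif(nz, 0.5, 20), 3)
    Matrix::Matrix(m, sparse = TRUE)
  })
}
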