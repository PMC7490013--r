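#' Gene-by-cell count container
#'
#' Lightweight container tying a sparse gene-by-cell count matrix to
#' per-cell metadata (age in weeks, replicate, sort gate or hashtag label,
#' sample of origin) and per-gene flags (ERCC spike-in, mitochondrial).
#' Normalisation ([normalize_cells()]) adds per-cell size factors and a
#' log10(normalised + 1) expression matrix.
#'
#' @param counts Non-negative integer matrix or `dgCMatrix`, genes in rows,
#'   cells in columns; dimnames required.
#' @param cell_meta data.frame with one row per cell (recycled defaults are
#'   created when omitted). Recognised columns: `age`, `replicate`,
#'   `sample`, `label`.
#' @param gene_meta data.frame with one row per gene; logical columns
#'   `is_ercc` and `is_mito` are created from the `ERCC-` and `mt-` name
#'   prefixes when omitted.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  if (!inherits(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene and cell names")
  }
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  n_cells <- ncol(counts)
  n_genes <- nrow(counts)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(counts))
  }
  if (nrow(cell_meta) != n_cells) {
    stopf("cell_meta must have one row per cell (%d != %d)",
          nrow(cell_meta), n_cells)
  }
  rownames(cell_meta) <- colnames(counts)
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(
      is_ercc = startsWith(rownames(counts), "ERCC-"),
      is_mito = startsWith(rownames(counts), "mt-"),
      row.names = rownames(counts)
    )
  }
  if (nrow(gene_meta) != n_genes) {
    stopf("gene_meta must have one row per gene (%d != %d)",
          nrow(gene_meta), n_genes)
  }
  rownames(gene_meta) <- rownames(counts)
  out <- list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
              size_factors = NULL, logcounts = NULL)
  class(out) <- "cell_matrix"
  out
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$size_factors)) "" else " (normalised)"))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Quality-control filtering of single-cell count matrices
#'
#' Removes poor-quality cells using mode-specific criteria.
#' \describe{
#'   \item{plate}{(Smart-seq2 with ERCC spike-ins) a cell fails when the
#'     ERCC contribution to its total transcriptome exceeds 40%, its depth
#'     is below 1e5 reads, or its sparsity (fraction of zero genes) exceeds
#'     97%.}
#'   \item{droplet}{a cell fails when its mitochondrial fraction exceeds the
#'     sample median by more than two median absolute deviations (one-sided,
#'     computed within each `sample`), or fewer than 1000 UMIs were
#'     detected.}
#' }
#'
#' @param x A [cell_matrix()].
#' @param mode `"plate"` or `"droplet"`.
#' @param thresholds Optional overrides: `max_ercc_frac` (0.40),
#'   `min_depth` (1e5), `max_sparsity` (0.97) for plate; `mito_nmads` (2),
#'   `min_umis` (1000) for droplet.
#' @return A list with `matrix` (the filtered `cell_matrix`) and `report`,
#'   a per-cell data.frame of QC metrics, the pass flag and failure reasons
#'   covering every input cell.
#' @export
qc_filter <- function(x, mode = c("plate", "droplet"), thresholds = list()) {
  mode <- match.arg(mode)
  if (!inherits(x, "cell_matrix")) stopf("'x' must be a cell_matrix")
  if (ncol(x$counts) == 0L) stopf("cannot QC an empty matrix")
  defaults <- list(max_ercc_frac = 0.40, min_depth = 1e5, max_sparsity = 0.97,
                   mito_nmads = 2, min_umis = 1000)
  thr <- utils::modifyList(defaults, thresholds)
  counts <- x$counts
  total <- Matrix::colSums(counts)
  n_genes <- nrow(counts)
  detected <- Matrix::colSums(counts > 0)
  sparsity <- 1 - detected / n_genes
  report <- data.frame(cell = colnames(counts), total = total,
                       sparsity = sparsity, row.names = NULL)
  reasons <- vector("list", ncol(counts))
  if (mode == "plate") {
    if (!"is_ercc" %in% names(x$gene_meta)) {
      stopf("plate-mode QC needs the 'is_ercc' gene flag")
    }
    ercc_frac <- ifelse(total > 0,
                        Matrix::colSums(counts[x$gene_meta$is_ercc, ,
                                               drop = FALSE]) / total, 1)
    report$ercc_frac <- ercc_frac
    fail_ercc <- ercc_frac > thr$max_ercc_frac
    fail_depth <- total < thr$min_depth
    fail_sparse <- sparsity > thr$max_sparsity
    for (i in which(fail_ercc)) reasons[[i]] <- c(reasons[[i]], "high_ercc")
    for (i in which(fail_depth)) reasons[[i]] <- c(reasons[[i]], "low_depth")
    for (i in which(fail_sparse)) reasons[[i]] <- c(reasons[[i]], "high_sparsity")
  } else {
    if (!"is_mito" %in% names(x$gene_meta)) {
      stopf("droplet-mode QC needs the 'is_mito' gene flag")
    }
    mito_frac <- ifelse(total > 0,
                        Matrix::colSums(counts[x$gene_meta$is_mito, ,
                                               drop = FALSE]) / total, 0)
    report$mito_frac <- mito_frac
    sample_id <- if ("sample" %in% names(x$cell_meta)) {
      as.character(x$cell_meta$sample)
    } else rep("all", ncol(counts))
    fail_mito <- logical(ncol(counts))
    for (s in unique(sample_id)) {
      in_s <- sample_id == s
      med <- median(mito_frac[in_s])
      cut <- med + thr$mito_nmads * mad(mito_frac[in_s])
      fail_mito[in_s] <- mito_frac[in_s] > cut
    }
    fail_umis <- total < thr$min_umis
    for (i in which(fail_mito)) reasons[[i]] <- c(reasons[[i]], "high_mito")
    for (i in which(fail_umis)) reasons[[i]] <- c(reasons[[i]], "low_umis")
  }
  report$pass <- lengths(reasons) == 0L
  report$reason <- vapply(reasons, function(r) {
    if (length(r)) paste(r, collapse = ";") else ""
  }, character(1L))
  keep <- report$pass
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$cell_meta <- x$cell_meta[keep, , drop = FALSE]
  out$size_factors <- NULL
  out$logcounts <- NULL
  list(matrix = out, report = report)
}

#' Size-factor normalisation with log10 transform
#'
#' Computes per-cell size factors and stores normalised expression
#' `log10(count / size_factor + 1)` on the object. `"library_size"` factors
#' are each cell's total count divided by the geometric mean of totals (so
#' factors multiply to 1); `"deconvolution"` delegates to the pooled
#' deconvolution estimator in the scran package when it is installed.
#'
#' @param x A QC-passed [cell_matrix()].
#' @param method `"library_size"` or `"deconvolution"`.
#' @return The `cell_matrix` with `size_factors` and `logcounts` populated.
#' @export
normalize_cells <- function(x, method = c("library_size", "deconvolution")) {
  method <- match.arg(method)
  if (!inherits(x, "cell_matrix")) stopf("'x' must be a cell_matrix")
  total <- Matrix::colSums(x$counts)
  if (any(total == 0)) {
    stopf("%d cell(s) have zero total counts; run qc_filter() first",
          sum(total == 0))
  }
  if (method == "library_size") {
    sf <- total / geo_mean(total)
  } else {
    if (!requireNamespace("scran", quietly = TRUE)) {
      stopf("method='deconvolution' needs the scran package; use 'library_size'")
    }
    sf <- scran::calculateSumFactors(x$counts)
    sf <- sf / geo_mean(sf)
  }
  norm <- x$counts %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(norm) <- dimnames(x$counts)
  logc <- norm
  logc@x <- log10(logc@x + 1) # sparse-safe: log10(0 + 1) = 0
  x$size_factors <- setNames(sf, colnames(x$counts))
  x$logcounts <- logc
  x$normcounts <- norm
  x
}

#' Highly variable gene selection
#'
#' Fits a mean-variance trend across genes on the log-normalised expression
#' (loess on the per-gene mean/variance scatter), tests each gene's excess
#' variance over the trend with a one-sided chi-square test, adjusts with
#' Benjamini-Hochberg and returns genes significant at `fdr`. When the
#' trend cannot be fitted (too few distinct means), the `fallback_k` genes
#' with the largest residual variance are returned with a warning.
#'
#' @param x A normalised [cell_matrix()], or a dense/sparse matrix of
#'   log-expression values (genes in rows).
#' @param fdr Benjamini-Hochberg threshold (default `1e-7`).
#' @param span Loess span for the trend fit.
#' @param fallback_k Number of genes returned by the degenerate fallback.
#' @return Character vector of gene names. The full per-gene table (mean,
#'   variance, trend, p, adjusted p) is attached as attribute `"stats"`.
#' @export
select_hvgs <- function(x, fdr = 1e-7, span = 0.3, fallback_k = 2000L) {
  expr <- if (inherits(x, "cell_matrix")) {
    if (is.null(x$logcounts)) stopf("normalise the matrix first")
    x$logcounts
  } else x
  n <- ncol(expr)
  if (nrow(expr) < 10L) stopf("need at least 10 genes")
  if (n < 3L) stopf("need at least 3 cells")
  mu <- Matrix::rowMeans(expr)
  v <- Matrix::rowMeans(expr^2) - mu^2
  v <- v * n / (n - 1)
  trend <- tryCatch({
    fit <- loess(v ~ mu, span = span, degree = 2,
                 family = "symmetric")
    pmax(predict(fit, mu), 1e-12)
  }, error = function(e) NULL)
  genes <- rownames(expr)
  if (is.null(trend) || all(v < 1e-12)) {
    warning("mean-variance trend fit degenerate; returning top genes by variance")
    ord <- order(v, decreasing = TRUE)
    return(genes[ord[seq_len(min(fallback_k, length(ord)))]])
  }
  stat <- (n - 1) * v / trend
  p <- pchisq(stat, df = n - 1, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  stats <- data.frame(gene = genes, mean = mu, var = v, trend = trend,
                      p = p, padj = padj, row.names = NULL)
  out <- genes[padj <= fdr]
  attr(out, "stats") <- stats
  out
}

#' Read and write a cell_matrix in MatrixMarket exchange format
#'
#' Writes `matrix.mtx`, `genes.tsv` (gene name + flags) and `cells.tsv`
#' (cell name + metadata) into `dir`; `read_cell_matrix()` reverses this.
#'
#' @param x A [cell_matrix()].
#' @param dir Directory (created if needed).
#' @return The directory path (write) or a `cell_matrix` (read).
#' @export
write_cell_matrix <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(cbind(gene = rownames(x$counts), x$gene_meta),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(cell = colnames(x$counts), x$cell_meta),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, cells$cell)
  cell_matrix(counts,
              cell_meta = cells[, setdiff(names(cells), "cell"), drop = FALSE],
              gene_meta = genes[, setdiff(names(genes), "gene"), drop = FALSE])
}
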