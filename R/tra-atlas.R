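#' Tau tissue-specificity index and TRA classification
#'
#' Computes, for every gene in a gene-by-tissue expression panel, the tau
#' index
#' \deqn{\tau = \frac{\sum_i (1 - \hat x_i)}{n - 1}, \qquad
#'       \hat x_i = \frac{x_i}{\max_j x_j}}
#' where \eqn{x_i} is the gene's expression in tissue \eqn{i} of \eqn{n}.
#' Tau is 0 for uniformly expressed genes and 1 for genes expressed in a
#' single tissue. Genes with \eqn{\tau \ge 0.8} are classed as
#' tissue-restricted antigens (TRA), genes with \eqn{\tau \le 0.4} as
#' constitutive, and the remainder as miscellaneous. Each TRA gene is
#' assigned the tissue in which it is maximally expressed (exact ties are
#' broken by panel column order and reported via a message).
#'
#' @param panel Non-negative matrix, genes in rows, >= 2 tissue columns.
#'   Per-tissue values are assumed pre-collapsed (e.g. maximum normalised
#'   expression over the tissue's samples, isoforms averaged).
#' @param tra_threshold,constitutive_threshold Class boundaries (0.8, 0.4).
#' @param min_expression Optional detectability floor: genes whose maximum
#'   expression falls below it are excluded like all-zero genes (default 0,
#'   off).
#' @return An object of class `tau_table`: a data.frame with `gene`, `tau`,
#'   `class` (`TRA`/`constitutive`/`miscellaneous`) and `tissue` (NA except
#'   for TRA genes). All-zero genes are excluded with a warning.
#' @examples
#' panel <- rbind(uniform = rep(2, 5), restricted = c(10, 5, 0, 0, 0))
#' colnames(panel) <- paste0("t", 1:5)
#' compute_tau_table(panel)
#' @export
compute_tau_table <- function(panel, tra_threshold = 0.8,
                              constitutive_threshold = 0.4,
                              min_expression = 0) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 2L) stopf("tau needs >= 2 tissues")
  if (any(panel < 0)) stopf("panel expression must be non-negative")
  if (is.null(rownames(panel))) stopf("panel must carry gene row names")
  if (is.null(colnames(panel))) {
    colnames(panel) <- sprintf("tissue%02d", seq_len(ncol(panel)))
  }
  mx <- apply(panel, 1L, max)
  drop <- mx <= min_expression
  if (any(drop)) {
    warning(sprintf("excluding %d gene(s) with no expression above %.3g",
                    sum(drop), min_expression), call. = FALSE)
    panel <- panel[!drop, , drop = FALSE]
    mx <- mx[!drop]
  }
  if (nrow(panel) == 0L) stopf("no genes left after excluding all-zero rows")
  n <- ncol(panel)
  xhat <- panel / mx
  tau <- rowSums(1 - xhat) / (n - 1)
  cls <- ifelse(tau >= tra_threshold, "TRA",
                ifelse(tau <= constitutive_threshold, "constitutive",
                       "miscellaneous"))
  top <- apply(panel, 1L, which.max) # first index on exact ties
  ties <- rowSums(panel == mx) > 1L
  if (any(ties & cls == "TRA")) {
    message(sprintf("%d TRA gene(s) had tied maximal tissues; first tissue kept",
                    sum(ties & cls == "TRA")))
  }
  out <- data.frame(
    gene = rownames(panel), tau = unname(tau), class = unname(cls),
    tissue = ifelse(cls == "TRA", colnames(panel)[top], NA_character_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("tau_table", "data.frame")
  out
}

#' Count tissue representation of TRA expression per cell
#'
#' For each cell, counts the TRA genes with log-expression above zero (i.e.
#' any non-zero normalised count) within each assigned tissue; these
#' per-cell counts are aggregated (summed) over cells of each (age,
#' replicate) group into "tissue counts" for downstream abundance
#' modelling. Also reports, per cell, the percentage of expressed genes
#' that are classed as TRA.
#'
#' @param x A normalised [cell_matrix()].
#' @param tau A [compute_tau_table()] result.
#' @return A list of class `tissue_counts`: `per_cell` (tissue x cell
#'   integer matrix), `aggregated` (data.frame: `age`, `replicate`,
#'   `tissue`, `count`), `pct_tra` (named per-cell percentage of expressed
#'   genes that are TRAs).
#' @export
count_tissue_representation <- function(x, tau) {
  if (!inherits(x, "cell_matrix")) stopf("'x' must be a cell_matrix")
  if (is.null(x$logcounts)) stopf("normalise the matrix first")
  if (!inherits(tau, "tau_table")) stopf("'tau' must be a tau_table")
  tra <- tau[tau$class == "TRA", , drop = FALSE]
  tra <- tra[tra$gene %in% rownames(x$logcounts), , drop = FALSE]
  expressed <- x$logcounts > 0
  n_expr <- Matrix::colSums(expressed)
  if (nrow(tra) == 0L) {
    warning("no TRA genes present in the matrix", call. = FALSE)
    per_cell <- matrix(0L, 0L, ncol(x$counts),
                       dimnames = list(NULL, colnames(x$counts)))
    pct <- setNames(rep(0, ncol(x$counts)), colnames(x$counts))
    agg <- data.frame(age = numeric(0), replicate = integer(0),
                      tissue = character(0), count = integer(0))
  } else {
    tissues <- sort(unique(tra$tissue))
    ind <- Matrix::sparseMatrix(
      i = match(tra$tissue, tissues), j = match(tra$gene, rownames(expressed)),
      x = 1, dims = c(length(tissues), nrow(expressed))
    )
    per_cell <- as.matrix(ind %*% expressed)
    dimnames(per_cell) <- list(tissues, colnames(x$counts))
    tra_expr <- Matrix::colSums(expressed[tra$gene, , drop = FALSE])
    pct <- setNames(ifelse(n_expr > 0, 100 * tra_expr / n_expr, 0),
                    colnames(x$counts))
    meta <- x$cell_meta
    if (!all(c("age", "replicate") %in% names(meta))) {
      stopf("cell metadata needs 'age' and 'replicate' for aggregation")
    }
    grp <- paste(meta$age, meta$replicate, sep = "|")
    agg_mat <- t(rowsum(t(per_cell), grp)) # tissue x group sums
    key <- do.call(rbind, strsplit(colnames(agg_mat), "|", fixed = TRUE))
    agg <- data.frame(
      age = rep(as.numeric(key[, 1]), each = length(tissues)),
      replicate = rep(key[, 2], each = length(tissues)),
      tissue = rep(tissues, times = ncol(agg_mat)),
      count = as.integer(agg_mat),
      stringsAsFactors = FALSE
    )
  }
  out <- list(per_cell = per_cell, aggregated = agg, pct_tra = pct)
  class(out) <- "tissue_counts"
  out
}

#' @export
print.tissue_counts <- function(x, ...) {
  cat(sprintf("<tissue_counts> %d tissues x %d cells; %d aggregated rows\n",
              nrow(x$per_cell), ncol(x$per_cell), nrow(x$aggregated)))
  invisible(x)
}
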