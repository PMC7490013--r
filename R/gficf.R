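#' Gene frequency - inverse cell frequency transform
#'
#' TF-IDF-style reweighting of a normalised gene-by-cell expression matrix
#' that boosts rarely expressed genes (such as promiscuously expressed
#' tissue-restricted antigens) and damps ubiquitous ones. The gene frequency
#' is `G_f = log2(C + pseudocount)` where `C` is the normalised count
#' matrix, the inverse cell frequency of gene x is
#' `ICF_x = log10(N / (1 + E_x))` with `N` cells and `E_x` cells expressing
#' x (count > 0), and the output is `G_f` scaled row-wise by `ICF`. Genes
#' expressed in all cells get a small negative ICF (`log10(N/(N+1))`) and
#' are retained, not clipped.
#'
#' @param x A normalised [cell_matrix()] (its `normcounts` are used) or a
#'   matrix of normalised counts, genes in rows.
#' @param pseudocount Added inside the log2 so zero counts map to zero
#'   weight (default 1).
#' @return An object of class `gficf_matrix`: the transformed dense matrix
#'   with attributes `icf` (per-gene weights), `n_cells` and `pseudocount`.
#' @examples
#' m <- matrix(rpois(90, 2), 10, 9,
#'             dimnames = list(paste0("g", 1:10), paste0("c", 1:9)))
#' g <- gficf_transform(m)
#' @export
gficf_transform <- function(x, pseudocount = 1) {
  mat <- if (inherits(x, "cell_matrix")) {
    if (is.null(x$normcounts)) stopf("normalise the matrix first")
    x$normcounts
  } else x
  n <- ncol(mat)
  if (n < 2L) stopf("GF-ICF needs at least 2 cells")
  e_x <- Matrix::rowSums(mat > 0)
  icf <- log10(n / (1 + e_x))
  gf <- log2(as.matrix(mat) + pseudocount)
  out <- gf * icf
  if (any(!is.finite(out))) stopf("GF-ICF produced non-finite values")
  structure(out, class = c("gficf_matrix", class(out)),
            icf = icf, n_cells = n, pseudocount = pseudocount)
}

# k-nearest-neighbour index matrix (n x k) by Euclidean distance on rows
knn_index <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)",
                    k, n)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
}

# optional PCA down to n_pcs dimensions (cells in rows)
maybe_pca <- function(pts, n_pcs) {
  if (is.null(n_pcs) || ncol(pts) <= n_pcs) return(pts)
  prcomp(pts, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
}

#' Shared-nearest-neighbour graph and Walktrap clustering
#'
#' Builds a k-nearest-neighbour graph on cells (optionally in PCA space),
#' converts it to a shared-nearest-neighbour (SNN) graph whose edge weights
#' are the Jaccard overlap of the two cells' neighbour sets (edges with zero
#' overlap are dropped), and partitions it with Walktrap random-walk
#' community detection.
#'
#' @param x Matrix with cells in columns (e.g. a [gficf_transform()] result
#'   or log-normalised expression).
#' @param k Neighbourhood size (10 for the plate data defaults, 31 for
#'   droplet data).
#' @param n_pcs Optional number of principal components to reduce to before
#'   computing distances (e.g. 20); `NULL` uses the input space directly.
#' @param steps Walktrap random-walk length (default 4).
#' @return A list of class `snn_clustering`: `labels` (integer cluster per
#'   cell, named), `graph` (the weighted igraph object), `k`, `n_pcs`,
#'   `modularity`.
#' @export
snn_walktrap <- function(x, k = 10L, n_pcs = NULL, steps = 4L) {
  pts <- maybe_pca(t(as.matrix(x)), n_pcs)
  n <- nrow(pts)
  nn <- knn_index(pts, k)
  # shared-neighbour counts via the neighbourhood indicator matrix
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x) # |A int B| / |A un B|
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  igraph::V(g)$name <- colnames(x)
  wt <- igraph::cluster_walktrap(g, steps = steps)
  labels <- setNames(as.integer(igraph::membership(wt)), colnames(x))
  out <- list(labels = labels, graph = g, k = k, n_pcs = n_pcs,
              modularity = max(wt$modularity))
  class(out) <- "snn_clustering"
  out
}

#' @export
print.snn_clustering <- function(x, ...) {
  cat(sprintf("<snn_clustering> %d cells, %d communities (k = %d)\n",
              length(x$labels), length(unique(x$labels)), x$k))
  invisible(x)
}

#' Consensus robustness of a clustering across parameterisations
#'
#' Re-clusters the same cells under a grid of parameterisations (with or
#' without the GF-ICF transform, different neighbourhood sizes, with or
#' without PCA) and summarises how often cells co-cluster. The consensus
#' matrix entry (i, j) is the fraction of parameterisations in which cells
#' i and j share a community; the robustness score is the mean off-diagonal
#' consensus within the clusters of the reference partition (the first grid
#' entry).
#'
#' @param norm_matrix Normalised count matrix (genes x cells), the common
#'   input to every parameterisation.
#' @param grid List of parameterisations, each a list with elements
#'   `gficf` (logical), `k`, and optional `n_pcs`.
#' @param pseudocount Passed to [gficf_transform()].
#' @return A list of class `consensus_result`: `consensus` (cell x cell
#'   matrix in `[0, 1]`), `score`, `partitions` (matrix of labels, one
#'   column per parameterisation).
#' @export
consensus_robustness <- function(norm_matrix,
                                 grid = list(list(gficf = TRUE, k = 10L),
                                             list(gficf = FALSE, k = 10L)),
                                 pseudocount = 1) {
  if (length(grid) < 2L) stopf("need >= 2 parameterisations")
  mat <- if (inherits(norm_matrix, "cell_matrix")) {
    if (is.null(norm_matrix$normcounts)) stopf("normalise the matrix first")
    norm_matrix$normcounts
  } else norm_matrix
  n <- ncol(mat)
  gficf_mat <- NULL
  partitions <- matrix(NA_integer_, nrow = n, ncol = length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    input <- if (isTRUE(cfg$gficf)) {
      if (is.null(gficf_mat)) gficf_mat <- gficf_transform(mat, pseudocount)
      gficf_mat
    } else {
      lg <- as.matrix(mat)
      log10(lg + 1)
    }
    cl <- snn_walktrap(input, k = cfg$k %||% 10L, n_pcs = cfg$n_pcs)
    partitions[, i] <- cl$labels
  }
  rownames(partitions) <- colnames(mat)
  consensus <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_along(grid)) {
    same <- outer(partitions[, i], partitions[, i], "==")
    consensus <- consensus + same
  }
  consensus <- consensus / length(grid)
  ref <- partitions[, 1]
  within <- vapply(unique(ref), function(cl) {
    idx <- which(ref == cl)
    if (length(idx) < 2L) return(1)
    block <- consensus[idx, idx]
    mean(block[upper.tri(block)])
  }, numeric(1L))
  out <- list(consensus = consensus, score = mean(within),
              partitions = partitions)
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d cells, %d parameterisations, score %.3f\n",
              nrow(x$consensus), ncol(x$partitions), x$score))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-cell cosine (L2) normalisation of a genes x cells matrix
cosine_normalize <- function(x) {
  nrm <- sqrt(Matrix::colSums(x^2))
  if (any(nrm == 0)) stopf("cannot cosine-normalise all-zero cells")
  as.matrix(x) %*% diag(1 / nrm, length(nrm))
}

#' k-nearest-neighbour label transfer between datasets
#'
#' Maps cluster labels from a labelled reference onto query cells. Both
#' matrices are restricted to their shared genes and cosine-normalised per
#' cell; an optional batch corrector (any function of two matrices
#' returning the corrected pair) is applied; each query cell then takes the
#' majority label among its `k` nearest reference cells, with ties broken
#' by the smallest mean distance to the tied labels' neighbours.
#'
#' @param reference_matrix,query_matrix Expression matrices, genes in rows.
#' @param reference_labels Vector of labels, one per reference cell.
#' @param k Number of neighbours (default 5).
#' @param corrector `NULL` (identity) or `function(ref, query)` returning
#'   `list(ref =, query =)`; `batch_center_correct()` is provided.
#' @return Character vector of transferred labels, one per query cell.
#' @export
knn_label_transfer <- function(reference_matrix, reference_labels,
                               query_matrix, k = 5L, corrector = NULL) {
  shared <- intersect(rownames(reference_matrix), rownames(query_matrix))
  if (length(shared) == 0L) stopf("reference and query share no genes")
  if (length(reference_labels) != ncol(reference_matrix)) {
    stopf("need one reference label per reference cell")
  }
  ref <- cosine_normalize(reference_matrix[shared, , drop = FALSE])
  qry <- cosine_normalize(query_matrix[shared, , drop = FALSE])
  if (!is.null(corrector)) {
    corrected <- corrector(ref, qry)
    ref <- corrected$ref
    qry <- corrected$query
  }
  k <- min(k, ncol(ref))
  labels <- as.character(reference_labels)
  # squared Euclidean cross-distances via the inner product
  cross <- crossprod(qry, ref)                    # query x reference
  d2 <- outer(Matrix::colSums(qry^2), Matrix::colSums(ref^2), "+") - 2 * cross
  out <- character(ncol(qry))
  for (i in seq_len(ncol(qry))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      mean_d <- vapply(top, function(lb) {
        mean(d2[i, nn[labels[nn] == lb]])
      }, numeric(1L))
      out[i] <- top[which.min(mean_d)]
    }
  }
  out
}

#' Per-batch mean-centering corrector for [knn_label_transfer()]
#'
#' Centres each gene within each dataset; a simple stand-in satisfying the
#' corrector interface where full mutual-nearest-neighbour correction is
#' not required.
#'
#' @param ref,query Cosine-normalised matrices, genes in rows.
#' @return `list(ref =, query =)`.
#' @export
batch_center_correct <- function(ref, query) {
  list(ref = ref - rowMeans(ref), query = query - rowMeans(query))
}
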