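#' Diffusion map embedding and diffusion pseudotime
#'
#' Builds a diffusion map on cells and computes diffusion pseudotime (DPT)
#' distances from a root cell. The transition kernel is Gaussian on the
#' union k-nearest-neighbour graph with local bandwidths (each cell's sigma
#' is its distance to the `ceiling(k/2)`-th neighbour), density-normalised
#' and row-normalised to a Markov matrix. Diffusion components (DCs) are
#' the non-trivial right eigenvectors; DPT between cells is the Euclidean
#' distance between their eigenvector coordinates weighted by
#' `lambda / (1 - lambda)`, i.e. the accumulated-transition (random walk)
#' formulation. The root defaults to the cell with the lowest DC1
#' coordinate — the apex of a bifurcating lineage.
#'
#' @param x Numeric matrix with cells in columns (log-normalised expression
#'   over highly variable genes, or any embedding with features in rows).
#' @param k Neighbourhood size for the kNN graph (default 21).
#' @param n_pcs Number of principal components to reduce to first (default
#'   20); `NULL` to use the input space.
#' @param root Column index of the root cell, or `NULL` for argmin DC1.
#' @param n_dcs Number of diffusion components kept (default 20, capped at
#'   n - 2).
#' @return An object of class `diffusion_embedding`: `dc` (cells x n_dcs),
#'   `dpt` (named, root has 0), `root`, `eigenvalues`, `k`, `n_pcs`.
#' @export
diffusion_pseudotime <- function(x, k = 21L, n_pcs = 20L, root = NULL,
                                 n_dcs = 20L) {
  pts <- maybe_pca(t(as.matrix(x)), n_pcs)
  n <- nrow(pts)
  if (n < k + 1L) stopf("need at least k + 1 = %d cells", k + 1L)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  sigma <- d[cbind(seq_len(n), nn[, ceiling(k / 2)])] # local bandwidth
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  mask <- matrix(FALSE, n, n)
  mask[cbind(rep(seq_len(n), k), as.vector(nn))] <- TRUE
  mask <- mask | t(mask) # union kNN graph
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(mask, mode = "undirected")
  )
  if (comp$no > 1L) {
    stopf("kNN graph is disconnected (%d components of sizes %s); increase k",
          comp$no, paste(comp$csize, collapse = ", "))
  }
  W <- matrix(0, n, n)
  W[mask] <- exp(-(d[mask]^2) / (outer(sigma, sigma)[mask]))
  diag(W) <- 0
  # density normalisation removes sampling-density bias before the walk
  q <- rowSums(W)
  K <- W / outer(q, q)
  dg <- rowSums(K)
  S <- K / sqrt(outer(dg, dg)) # symmetric conjugate of the Markov matrix
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors / sqrt(dg) # right eigenvectors of the Markov matrix
  # normalise so the trivial eigenvector is constant 1
  psi <- psi / psi[1, 1]
  lambda <- eig$values
  n_use <- min(n_dcs, n - 2L)
  idx <- seq.int(2L, 1L + n_use)
  lam <- pmin(lambda[idx], 1 - 1e-12)
  w <- lam / (1 - lam)
  dc <- sweep(psi[, idx, drop = FALSE], 2L, lam, "*")
  rownames(dc) <- rownames(pts)
  colnames(dc) <- sprintf("DC%d", seq_len(n_use))
  if (is.null(root)) {
    root <- which.min(dc[, 1])
  } else if (root < 1L || root > n) {
    stopf("root must index a cell (1..%d)", n)
  }
  delta <- sweep(psi[, idx, drop = FALSE], 2L, psi[root, idx], "-")
  dpt <- sqrt(rowSums(sweep(delta, 2L, w, "*")^2))
  names(dpt) <- rownames(pts)
  out <- list(dc = dc, dpt = dpt, root = root, eigenvalues = lambda,
              k = k, n_pcs = n_pcs)
  class(out) <- "diffusion_embedding"
  out
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("<diffusion_embedding> %d cells, %d DCs, root cell %d\n",
              nrow(x$dc), ncol(x$dc), x$root))
  invisible(x)
}

#' Cell density along diffusion pseudotime
#'
#' Gaussian kernel density estimate of the DPT distribution, evaluated at a
#' fixed number of points equal to 1% of cells (rounded up), spanning the
#' DPT range. High-density regions along the trajectory correspond to
#' meta-stable differentiation states.
#'
#' @param dpt_values Numeric DPT vector (>= 100 cells).
#' @param points_fraction Fraction of cells determining the number of
#'   evaluation points (default 0.01).
#' @param bw Bandwidth: `"nrd0"` (Silverman's rule, default) or a number.
#' @return data.frame with columns `dpt` (evaluation points) and `density`.
#' @export
dpt_density <- function(dpt_values, points_fraction = 0.01, bw = "nrd0") {
  n <- length(dpt_values)
  if (n < 100L) stopf("need >= 100 cells for the 1%% evaluation rule")
  if (diff(range(dpt_values)) == 0) {
    stopf("DPT values are constant; density is degenerate")
  }
  n_points <- ceiling(points_fraction * n)
  dens <- density(dpt_values, bw = bw, n = n_points,
                  from = min(dpt_values), to = max(dpt_values))
  data.frame(dpt = dens$x, density = dens$y)
}

#' Assign cells to meta-stable states along pseudotime
#'
#' Fits a univariate Gaussian mixture model (unequal variances, via the
#' mclust package) to DPT distances and assigns every cell to its
#' maximum-responsibility component. States are relabelled in order of
#' increasing mean DPT, so state 1 is always the earliest along the
#' trajectory.
#'
#' @param dpt_values Numeric DPT vector (length >= 10 * n_components).
#' @param n_components Number of states, typically 2 or 3.
#' @param seed Seed (the fit is deterministic, kept for interface
#'   stability).
#' @param age,replicate Optional per-cell annotations; when both are given
#'   the result includes per (state, age, replicate) cell counts.
#' @return An object of class `state_table`: `state` (per cell),
#'   `parameters` (per state: mean, sd, weight), `counts` (data.frame or
#'   NULL), `loglik`.
#' @importFrom mclust Mclust mclustBIC
#' @export
assign_states <- function(dpt_values, n_components, seed = 1L, age = NULL,
                          replicate = NULL) {
  n <- length(dpt_values)
  if (n < 10L * n_components) {
    stopf("need >= %d cells for %d components", 10L * n_components,
          n_components)
  }
  if (diff(range(dpt_values)) == 0) {
    stopf("DPT values are constant; mixture model is degenerate")
  }
  fit <- with_seed(seed, {
    tryCatch(
      Mclust(dpt_values, G = n_components, modelNames = "V",
             verbose = FALSE),
      error = function(e) NULL
    )
  })
  if (is.null(fit)) {
    stopf("gaussian mixture fit failed for %d components on %d cells",
          n_components, n)
  }
  means <- fit$parameters$mean
  ord <- order(means)
  relabel <- match(seq_len(n_components), ord)
  state <- relabel[fit$classification]
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, n_components)
  params <- data.frame(
    state = seq_len(n_components),
    mean = means[ord],
    sd = sds[ord],
    weight = fit$parameters$pro[ord],
    row.names = NULL
  )
  counts <- NULL
  if (!is.null(age) && !is.null(replicate)) {
    counts <- as.data.frame(table(state = state, age = age,
                                  replicate = replicate),
                            stringsAsFactors = FALSE)
    names(counts)[4] <- "count"
    counts$state <- as.integer(counts$state)
    counts$age <- as.numeric(counts$age)
  }
  out <- list(state = state, parameters = params, counts = counts,
              loglik = fit$loglik)
  class(out) <- "state_table"
  out
}

#' @export
print.state_table <- function(x, ...) {
  cat(sprintf("<state_table> %d cells in %d states (means: %s)\n",
              length(x$state), nrow(x$parameters),
              paste(sprintf("%.2f", x$parameters$mean), collapse = ", ")))
  invisible(x)
}
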