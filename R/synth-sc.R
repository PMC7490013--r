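#' Specification for synthetic single-cell count matrices
#'
#' Describes a gene-by-cell counts experiment with discrete subtype
#' structure, age-varying composition and an optional block of
#' tissue-restricted antigen (TRA) genes expressed by one subtype —
#' the statistical structure the clustering, abundance and promiscuous
#' gene expression analyses assume.
#'
#' Counts are negative binomial around per-cluster mean profiles: baseline
#' gene means are log-normal, each cluster up-regulates its own marker genes
#' by `2^marker_lfc`, and TRA genes are expressed only in `tra_cluster`.
#' ERCC spike-in genes share a constant mean across cells; mitochondrial
#' genes are ordinary genes named with the `mt-` prefix.
#'
#' @param n_genes Total genes, including ERCC/mito/TRA blocks.
#' @param cells data.frame with columns `age` (weeks), `replicate` and
#'   `n_cells` (> 0) giving cells per (age, replicate).
#' @param n_clusters Number of cell subtypes.
#' @param cluster_props Either `NULL` (uniform at every age) or a matrix
#'   with one row per distinct age (rownames = age) and one column per
#'   cluster; rows must sum to 1.
#' @param markers_per_cluster,marker_lfc Marker genes per cluster and their
#'   log2 fold change above baseline.
#' @param tra_tissues,tra_genes_per_tissue,tra_cluster TRA block: number of
#'   tissues, genes assigned per tissue, and the (single) cluster expressing
#'   them. `tra_tissues = 0` disables the block.
#' @param base_mean_log Mean/sd of the log-normal baseline gene means,
#'   `c(meanlog, sdlog)`.
#' @param dispersion Negative binomial dispersion (variance = mu + mu^2 *
#'   dispersion).
#' @param dropout Probability that any observed count is zeroed
#'   (independent thinning); `1` yields an all-zero matrix.
#' @param ercc_frac,mito_frac Fractions of genes flagged ERCC/mitochondrial.
#' @param depth_factor Multiplies all gene means (sequencing depth knob).
#' @param cell_depth_sdlog Log-normal sd of per-cell capture efficiency;
#'   scales every gene's mean per cell, giving the depth variation that
#'   size-factor normalisation removes (0 disables).
#' @param seed Integer seed.
#' @return An object of class `sc_count_spec`.
#' @export
sc_count_spec <- function(n_genes = 2000L,
                          cells = data.frame(
                            age = rep(c(1, 4, 16, 32, 52), each = 2),
                            replicate = rep(1:2, times = 5),
                            n_cells = 50L
                          ),
                          n_clusters = 5L,
                          cluster_props = NULL,
                          markers_per_cluster = 40L,
                          marker_lfc = 3,
                          tra_tissues = 0L,
                          tra_genes_per_tissue = 10L,
                          tra_cluster = NULL,
                          base_mean_log = c(0.5, 1),
                          dispersion = 0.3,
                          dropout = 0,
                          ercc_frac = 0.02,
                          mito_frac = 0.02,
                          depth_factor = 1,
                          cell_depth_sdlog = 0.3,
                          seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), cells = cells,
               n_clusters = as.integer(n_clusters),
               cluster_props = cluster_props,
               markers_per_cluster = as.integer(markers_per_cluster),
               marker_lfc = marker_lfc,
               tra_tissues = as.integer(tra_tissues),
               tra_genes_per_tissue = as.integer(tra_genes_per_tissue),
               tra_cluster = tra_cluster,
               base_mean_log = base_mean_log, dispersion = dispersion,
               dropout = dropout, ercc_frac = ercc_frac,
               mito_frac = mito_frac, depth_factor = depth_factor,
               cell_depth_sdlog = cell_depth_sdlog,
               seed = as.integer(seed))
  class(spec) <- "sc_count_spec"
  validate_sc_spec(spec)
  spec
}

validate_sc_spec <- function(spec) {
  cells <- spec$cells
  if (!all(c("age", "replicate", "n_cells") %in% names(cells))) {
    stopf("'cells' needs columns age, replicate, n_cells")
  }
  if (any(cells$n_cells < 1L)) {
    stopf("every (age, replicate) group needs at least one cell")
  }
  if (spec$n_clusters < 1L) stopf("need >= 1 cluster")
  props <- spec$cluster_props
  if (!is.null(props)) {
    if (ncol(props) != spec$n_clusters) {
      stopf("cluster_props needs one column per cluster")
    }
    if (is.null(rownames(props))) stopf("cluster_props needs age rownames")
    if (any(abs(rowSums(props) - 1) > 1e-8) || any(props < 0)) {
      stopf("cluster proportions must be non-negative and sum to 1 per age")
    }
    missing_age <- setdiff(as.character(unique(cells$age)), rownames(props))
    if (length(missing_age)) {
      stopf("cluster_props lacks rows for age(s): %s",
            paste(missing_age, collapse = ", "))
    }
  }
  if (spec$dropout < 0 || spec$dropout > 1) stopf("dropout must be in [0, 1]")
  if (spec$tra_tissues > 0L &&
      (is.null(spec$tra_cluster) || spec$tra_cluster > spec$n_clusters)) {
    stopf("tra_cluster must name an existing cluster when TRA genes are present")
  }
  n_special <- ceiling(spec$n_genes * (spec$ercc_frac + spec$mito_frac)) +
    spec$tra_tissues * spec$tra_genes_per_tissue +
    spec$n_clusters * spec$markers_per_cluster
  if (n_special > spec$n_genes) {
    stopf("marker/TRA/spike-in blocks need more genes than n_genes provides")
  }
  invisible(spec)
}

#' Generate a synthetic single-cell count matrix with known structure
#'
#' Draws counts according to an [sc_count_spec()]. The ground truth (cluster
#' label per cell, TRA tissue per gene, marker assignments) is returned in a
#' separate `truth` element and is never written into the `cell_matrix`
#' consumed by pipeline stages.
#'
#' @param spec An [sc_count_spec()].
#' @return A list of class `sc_sim` with elements `matrix` (a
#'   [cell_matrix()]) and `truth` (list: `cluster` per cell, `tra_tissue`
#'   named per TRA gene, `markers` named list per cluster, `degenerate`
#'   flag set when the matrix is all zeros).
#' @export
gen_sc_counts <- function(spec) {
  if (!inherits(spec, "sc_count_spec")) stopf("'spec' must be an sc_count_spec")
  validate_sc_spec(spec)
  with_seed(spec$seed, {
    n_ercc <- ceiling(spec$n_genes * spec$ercc_frac)
    n_mito <- ceiling(spec$n_genes * spec$mito_frac)
    n_tra <- spec$tra_tissues * spec$tra_genes_per_tissue
    n_plain <- spec$n_genes - n_ercc - n_mito - n_tra
    gene_names <- c(
      sprintf("Gene%04d", seq_len(n_plain)),
      if (n_tra) sprintf("Tra%03d", seq_len(n_tra)),
      if (n_mito) sprintf("mt-Gene%02d", seq_len(n_mito)),
      if (n_ercc) sprintf("ERCC-%05d", seq_len(n_ercc))
    )
    is_tra <- grepl("^Tra", gene_names)
    is_mito <- startsWith(gene_names, "mt-")
    is_ercc <- startsWith(gene_names, "ERCC-")
    base_mu <- rlnorm(spec$n_genes, spec$base_mean_log[1],
                      spec$base_mean_log[2]) * spec$depth_factor
    base_mu[is_ercc] <- mean(base_mu) # spike-ins: flat, cell-independent
    # per-cluster mean profiles
    mu <- matrix(base_mu, nrow = spec$n_genes, ncol = spec$n_clusters)
    plain_idx <- which(!is_tra & !is_ercc)
    markers <- vector("list", spec$n_clusters)
    free <- plain_idx
    for (k in seq_len(spec$n_clusters)) {
      pick <- free[seq_len(min(spec$markers_per_cluster, length(free)))]
      free <- setdiff(free, pick)
      markers[[k]] <- gene_names[pick]
      mu[pick, k] <- mu[pick, k] * 2^spec$marker_lfc
      mu[pick, -k] <- mu[pick, -k] * 2^(-spec$marker_lfc / 2)
    }
    tra_tissue <- NULL
    if (n_tra) {
      tissue_of <- rep(sprintf("tissue%02d", seq_len(spec$tra_tissues)),
                       each = spec$tra_genes_per_tissue)
      tra_tissue <- setNames(tissue_of, gene_names[is_tra])
      mu[is_tra, ] <- 0.01 # near-silent outside the expressing cluster
      mu[is_tra, spec$tra_cluster] <- rlnorm(n_tra, spec$base_mean_log[1] + 1,
                                             0.5) * spec$depth_factor
    }
    # cells: cluster composition per age
    cells <- spec$cells
    ages <- as.character(cells$age)
    clusters <- integer(0)
    meta <- list()
    for (i in seq_len(nrow(cells))) {
      p <- if (is.null(spec$cluster_props)) {
        rep(1 / spec$n_clusters, spec$n_clusters)
      } else spec$cluster_props[ages[i], ]
      ki <- sample.int(spec$n_clusters, cells$n_cells[i], replace = TRUE,
                       prob = p)
      clusters <- c(clusters, ki)
      meta[[i]] <- data.frame(age = cells$age[i],
                              replicate = cells$replicate[i],
                              n = cells$n_cells[i])
    }
    meta <- do.call(rbind, meta)
    cell_meta <- data.frame(
      age = rep(meta$age, meta$n),
      replicate = rep(meta$replicate, meta$n)
    )
    cell_meta$sample <- paste0("age", cell_meta$age, "_rep", cell_meta$replicate)
    n_cells <- nrow(cell_meta)
    size <- 1 / spec$dispersion
    depth <- if (spec$cell_depth_sdlog > 0) {
      rlnorm(n_cells, 0, spec$cell_depth_sdlog)
    } else rep(1, n_cells)
    counts <- matrix(0L, nrow = spec$n_genes, ncol = n_cells)
    for (k in sort(unique(clusters))) {
      cols <- which(clusters == k)
      counts[, cols] <- rnbinom(spec$n_genes * length(cols),
                                mu = mu[, k] %o% depth[cols], size = size)
    }
    if (spec$dropout > 0) {
      keep <- rbinom(length(counts), 1L, 1 - spec$dropout)
      counts <- counts * keep
    }
    dimnames(counts) <- list(gene_names,
                             sprintf("cell%05d", seq_len(n_cells)))
    gene_meta <- data.frame(is_ercc = is_ercc, is_mito = is_mito,
                            row.names = gene_names)
    mat <- cell_matrix(counts, cell_meta = cell_meta, gene_meta = gene_meta)
    degenerate <- sum(counts) == 0
    if (degenerate) {
      warning("generated matrix is all zeros (degenerate)", call. = FALSE)
    }
    out <- list(
      matrix = mat,
      truth = list(cluster = setNames(clusters, colnames(counts)),
                   tra_tissue = tra_tissue, markers = markers,
                   degenerate = degenerate)
    )
    class(out) <- "sc_sim"
    out
  })
}
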