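#' Negative binomial background threshold for one hashtag
#'
#' Fits a negative binomial distribution to the background counts of a
#' hashtag — i.e. the raw counts of all barcodes except those in
#' `excluded_idx` — and returns the smallest integer count `q` whose
#' cumulative probability reaches `quantile`. The fit is maximum
#' likelihood initialised at the method-of-moments estimate
#' (`size = mean^2 / (variance - mean)`); the likelihood step keeps the
#' threshold stable when a few signal barcodes slip past the exclusions,
#' where raw moments would inflate it. If the likelihood fit fails the
#' moment estimate is used directly (`"nb_mom"`). When the sample variance
#' does not exceed the mean a Poisson quantile is used instead (flagged
#' `"poisson"`), or, for zero variance, the constant value itself
#' (`"degenerate"`).
#'
#' @param counts_for_hto Integer vector of raw counts for one HTO across
#'   all barcodes.
#' @param excluded_idx Indices of barcodes excluded from the background
#'   (presumed signal cells and top-count outliers).
#' @param quantile Threshold quantile (default 0.99).
#' @return A list with `q`, `mu`, `size` (NA unless negative binomial) and
#'   `method` in `"nb_ml"`, `"nb_mom"`, `"poisson"`, `"degenerate"`.
#' @export
fit_background_threshold <- function(counts_for_hto, excluded_idx = integer(0),
                                     quantile = 0.99) {
  if (quantile < 0 || quantile > 1) stopf("quantile must lie in [0, 1]")
  bg <- if (length(excluded_idx)) counts_for_hto[-excluded_idx] else counts_for_hto
  if (length(bg) < 20L) {
    stopf("need >= 20 background barcodes to fit a threshold (have %d)",
          length(bg))
  }
  mu <- mean(bg)
  v <- var(bg)
  if (v == 0) {
    return(list(q = bg[1], mu = mu, size = NA_real_, method = "degenerate"))
  }
  if (v <= mu) {
    return(list(q = qpois(quantile, lambda = mu), mu = mu, size = NA_real_,
                method = "poisson"))
  }
  size <- mu^2 / (v - mu)
  ml <- tryCatch(
    suppressWarnings(
      MASS::fitdistr(bg, "negative binomial",
                     start = list(size = size, mu = mu),
                     lower = c(1e-4, 1e-4))
    ),
    error = function(e) NULL
  )
  if (!is.null(ml) && all(is.finite(ml$estimate))) {
    return(list(q = qnbinom(quantile, mu = ml$estimate[["mu"]],
                            size = ml$estimate[["size"]]),
                mu = ml$estimate[["mu"]], size = ml$estimate[["size"]],
                method = "nb_ml"))
  }
  list(q = qnbinom(quantile, mu = mu, size = size), mu = mu, size = size,
       method = "nb_mom")
}

#' Demultiplex hashtag-oligo counts
#'
#' Implements a per-sample hashtag demultiplexing algorithm for pooled
#' droplet experiments:
#' \enumerate{
#'   \item normalise HTO counts across cell barcodes to counts per million
#'     (CPM) over the sample's expected hashtags;
#'   \item cluster barcodes on CPM with k-means, `k` = number of expected
#'     hashtags (10 restarts, seeded);
#'   \item for each hashtag, exclude the k-means partition with the highest
#'     mean CPM for that hashtag together with the `top_trim` fraction of
#'     barcodes with the highest raw counts, and fit the negative binomial
#'     background threshold `q` at `quantile`
#'     ([fit_background_threshold()]);
#'   \item assign the hashtag to every barcode with raw count `>= q`;
#'   \item call barcodes with exactly one assigned hashtag `Singlet`, more
#'     than one `Multiplet`, none `Dropout`.
#' }
#' Clustering uses CPM while thresholds are fitted to and applied on raw
#' counts; the two scales are intentional and easy to confuse.
#'
#' @param counts Integer matrix, hashtags in rows, barcodes in columns.
#' @param quantile Background quantile defining `q` (default 0.99).
#' @param top_trim Fraction of top-count barcodes excluded from each
#'   hashtag's background fit (default 0.005).
#' @param expected_htos Hashtags expected in this sample (default: all
#'   rows).
#' @param seed Seed for the k-means restarts.
#' @return An object of class `hto_assignment`: `calls` (data.frame:
#'   `barcode`, `call`, `assigned` as comma-separated hashtags, `n_assigned`),
#'   `thresholds` (per hashtag: `q`, `mu`, `size`, `method`), `kmeans_cluster`
#'   (per barcode), plus the parameters used.
#' @examples
#' sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 100,
#'                                    n_doublets = 10, n_empty = 10))
#' dmx <- hto_demux(sim$counts)
#' table(dmx$calls$call)
#' @export
hto_demux <- function(counts, quantile = 0.99, top_trim = 0.005,
                      expected_htos = rownames(counts), seed = 1L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry HTO row names and barcode column names")
  }
  missing <- setdiff(expected_htos, rownames(counts))
  if (length(missing)) {
    stopf("expected HTOs absent from the matrix: %s",
          paste(missing, collapse = ", "))
  }
  counts <- counts[expected_htos, , drop = FALSE]
  n_htos <- nrow(counts)
  n_bc <- ncol(counts)
  if (n_htos < 2L) stopf("need >= 2 HTOs to demultiplex")
  if (n_bc < 10L * n_htos) {
    stopf("need >= 10 barcodes per HTO (have %d for %d HTOs)", n_bc, n_htos)
  }
  if (anyDuplicated(colnames(counts))) stopf("barcodes must be unique")
  total <- colSums(counts)
  cpm <- counts
  pos <- total > 0
  cpm[, pos] <- sweep(counts[, pos, drop = FALSE], 2L, total[pos], "/") * 1e6
  cpm[, !pos] <- 0
  km <- with_seed(seed, {
    for (try in 1:3) {
      fit <- tryCatch(kmeans(t(cpm), centers = n_htos, nstart = 10L),
                      error = function(e) NULL)
      if (!is.null(fit)) break
      message("k-means failed (empty cluster?); re-seeding")
    }
    if (is.null(fit)) stopf("k-means failed after re-seeding")
    fit
  })
  part <- km$cluster
  thresholds <- data.frame(hto = rownames(counts), q = NA_real_,
                           mu = NA_real_, size = NA_real_,
                           method = NA_character_, stringsAsFactors = FALSE)
  assigned <- matrix(FALSE, n_htos, n_bc, dimnames = dimnames(counts))
  n_top <- ceiling(top_trim * n_bc)
  for (h in seq_len(n_htos)) {
    raw <- counts[h, ]
    mean_cpm <- tapply(cpm[h, ], part, mean)
    signal_part <- as.integer(names(mean_cpm)[which.max(mean_cpm)])
    excl <- which(part == signal_part)
    top_idx <- order(raw, decreasing = TRUE)[seq_len(n_top)]
    excl <- union(excl, top_idx)
    fit <- fit_background_threshold(raw, excl, quantile)
    thresholds$q[h] <- fit$q
    thresholds$mu[h] <- fit$mu
    thresholds$size[h] <- fit$size
    thresholds$method[h] <- fit$method
    assigned[h, ] <- raw >= fit$q
  }
  n_assigned <- colSums(assigned)
  call <- ifelse(n_assigned == 1L, "Singlet",
                 ifelse(n_assigned > 1L, "Multiplet", "Dropout"))
  assigned_str <- apply(assigned, 2L, function(a) {
    paste(rownames(counts)[a], collapse = ",")
  })
  out <- list(
    calls = data.frame(barcode = colnames(counts), call = call,
                       assigned = assigned_str, n_assigned = n_assigned,
                       row.names = NULL, stringsAsFactors = FALSE),
    thresholds = thresholds,
    kmeans_cluster = setNames(part, colnames(counts)),
    quantile = quantile, top_trim = top_trim, seed = seed
  )
  class(out) <- "hto_assignment"
  out
}

#' @export
print.hto_assignment <- function(x, ...) {
  tab <- table(factor(x$calls$call, c("Singlet", "Multiplet", "Dropout")))
  cat(sprintf("<hto_assignment> %d barcodes: %d singlets, %d multiplets, %d dropouts\n",
              nrow(x$calls), tab["Singlet"], tab["Multiplet"], tab["Dropout"]))
  invisible(x)
}
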