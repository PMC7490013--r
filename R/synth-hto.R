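#' Specification for synthetic hashtag-oligo count mixtures
#'
#' Describes an HTO-by-barcode counts experiment with known
#' singlet/doublet/empty composition. Every barcode receives negative
#' binomial background counts on every HTO; singlets add negative binomial
#' signal counts on their own HTO, doublets on two distinct HTOs, and empty
#' droplets carry background only.
#'
#' @param n_htos Number of hashtags (>= 2).
#' @param n_singlets Singlets per HTO (scalar or length-`n_htos` vector).
#' @param n_doublets,n_empty Numbers of doublet and empty barcodes.
#' @param signal_mean,signal_size Negative binomial mean and size
#'   (dispersion = 1/size) of the hashtag signal.
#' @param background_mean,background_size Background distribution.
#' @param seed Integer seed.
#' @return An object of class `hto_mix_spec`.
#' @export
hto_mix_spec <- function(n_htos = 6L, n_singlets = 300L, n_doublets = 60L,
                         n_empty = 30L, signal_mean = 500, signal_size = 10,
                         background_mean = 5, background_size = 1,
                         seed = 1L) {
  spec <- list(n_htos = as.integer(n_htos),
               n_singlets = rep(as.integer(n_singlets),
                                length.out = as.integer(n_htos)),
               n_doublets = as.integer(n_doublets),
               n_empty = as.integer(n_empty),
               signal_mean = signal_mean, signal_size = signal_size,
               background_mean = background_mean,
               background_size = background_size,
               seed = as.integer(seed))
  class(spec) <- "hto_mix_spec"
  if (spec$n_htos < 2L) stopf("need >= 2 HTOs")
  if (spec$signal_mean <= 0 || spec$background_mean <= 0) {
    stopf("signal and background means must be positive")
  }
  if (spec$signal_size <= 0 || spec$background_size <= 0) {
    stopf("negative binomial size (inverse dispersion) must be positive")
  }
  if (any(c(spec$n_singlets, spec$n_doublets, spec$n_empty) < 0L)) {
    stopf("barcode counts cannot be negative")
  }
  spec
}

#' Generate synthetic HTO counts with known barcode identities
#'
#' @param spec An [hto_mix_spec()].
#' @return A list of class `hto_sim`: `counts` (HTO x barcode integer
#'   matrix) and `truth` (data.frame with `barcode`, `type` in
#'   singlet/doublet/empty, `hto1`, `hto2`).
#' @export
gen_hto_counts <- function(spec) {
  if (!inherits(spec, "hto_mix_spec")) stopf("'spec' must be an hto_mix_spec")
  with_seed(spec$seed, {
    htos <- sprintf("HTO%d", seq_len(spec$n_htos))
    n_bc <- sum(spec$n_singlets) + spec$n_doublets + spec$n_empty
    if (n_bc == 0L) stopf("spec yields zero barcodes")
    counts <- matrix(
      rnbinom(spec$n_htos * n_bc, mu = spec$background_mean,
              size = spec$background_size),
      nrow = spec$n_htos
    )
    type <- c(rep("singlet", sum(spec$n_singlets)),
              rep("doublet", spec$n_doublets),
              rep("empty", spec$n_empty))
    hto1 <- rep(NA_character_, n_bc)
    hto2 <- rep(NA_character_, n_bc)
    hto1[type == "singlet"] <- rep(htos, spec$n_singlets)
    if (spec$n_doublets > 0L) {
      pairs <- replicate(spec$n_doublets, sample.int(spec$n_htos, 2L))
      hto1[type == "doublet"] <- htos[pairs[1, ]]
      hto2[type == "doublet"] <- htos[pairs[2, ]]
    }
    add_signal <- function(bc_idx, hto_name) {
      i <- match(hto_name, htos)
      counts[cbind(i, bc_idx)] <<- counts[cbind(i, bc_idx)] +
        rnbinom(length(bc_idx), mu = spec$signal_mean, size = spec$signal_size)
    }
    sing <- which(type == "singlet")
    if (length(sing)) add_signal(sing, hto1[sing])
    doub <- which(type == "doublet")
    if (length(doub)) {
      add_signal(doub, hto1[doub])
      add_signal(doub, hto2[doub])
    }
    # shuffle so barcode order carries no information
    ord <- sample.int(n_bc)
    counts <- counts[, ord, drop = FALSE]
    truth <- data.frame(barcode = sprintf("BC%05d", seq_len(n_bc)),
                        type = type[ord], hto1 = hto1[ord], hto2 = hto2[ord],
                        stringsAsFactors = FALSE)
    dimnames(counts) <- list(htos, truth$barcode)
    out <- list(counts = counts, truth = truth)
    class(out) <- "hto_sim"
    out
  })
}
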