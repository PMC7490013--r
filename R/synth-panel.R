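#' Generate a synthetic gene-by-tissue expression panel
#'
#' Builds an expression panel (genes x tissues, non-negative) containing
#' blocks with known tissue-specificity structure, emulating a
#' multi-tissue expression atlas collapsed to broad tissue groups:
#' \describe{
#'   \item{single}{expressed in exactly one tissue (tau = 1).}
#'   \item{uniform}{identical expression in every tissue (tau = 0).}
#'   \item{graded}{geometrically decaying profile across tissues
#'     (intermediate tau, computable from the decay rate).}
#'   \item{random}{log-normal noise profiles.}
#' }
#'
#' @param n_single,n_uniform,n_graded,n_random Genes per block.
#' @param n_tissues Number of tissue groups (default 27).
#' @param graded_rate Geometric decay rate of the graded profiles in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `tissue_panel_sim`: `panel` (matrix, genes x
#'   tissues) and `truth` (data.frame: `gene`, `class` naming the block,
#'   `tissue` the intended argmax tissue or NA).
#' @export
gen_tissue_panel <- function(n_single = 30L, n_uniform = 30L, n_graded = 30L,
                             n_random = 60L, n_tissues = 27L,
                             graded_rate = 0.5, seed = 1L) {
  if (n_tissues < 2L) stopf("need >= 2 tissues")
  if (graded_rate <= 0 || graded_rate >= 1) {
    stopf("graded_rate must lie strictly between 0 and 1")
  }
  with_seed(seed, {
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    blocks <- list()
    truth <- list()
    add <- function(mat, class, tissue) {
      blocks[[length(blocks) + 1L]] <<- mat
      truth[[length(truth) + 1L]] <<- data.frame(
        gene = rownames(mat), class = class, tissue = tissue,
        stringsAsFactors = FALSE
      )
    }
    if (n_single > 0L) {
      m <- matrix(0, n_single, n_tissues)
      home <- sample.int(n_tissues, n_single, replace = TRUE)
      m[cbind(seq_len(n_single), home)] <- rlnorm(n_single, 2, 0.5)
      rownames(m) <- sprintf("single%03d", seq_len(n_single))
      add(m, "single", tissues[home])
    }
    if (n_uniform > 0L) {
      lvl <- rlnorm(n_uniform, 2, 0.5)
      m <- matrix(lvl, n_uniform, n_tissues)
      rownames(m) <- sprintf("uniform%03d", seq_len(n_uniform))
      add(m, "uniform", NA_character_)
    }
    if (n_graded > 0L) {
      top <- rlnorm(n_graded, 2, 0.5)
      prof <- outer(top, graded_rate^(seq_len(n_tissues) - 1L))
      home <- sample.int(n_tissues, n_graded, replace = TRUE)
      m <- matrix(0, n_graded, n_tissues)
      for (i in seq_len(n_graded)) {
        # rotate so the peak sits in the gene's home tissue
        m[i, ] <- prof[i, ((seq_len(n_tissues) - home[i]) %% n_tissues) + 1L]
      }
      rownames(m) <- sprintf("graded%03d", seq_len(n_graded))
      add(m, "graded", tissues[home])
    }
    if (n_random > 0L) {
      m <- matrix(rlnorm(n_random * n_tissues, 0, 1), n_random, n_tissues)
      rownames(m) <- sprintf("random%03d", seq_len(n_random))
      add(m, "random", NA_character_)
    }
    panel <- do.call(rbind, blocks)
    colnames(panel) <- tissues
    out <- list(panel = panel, truth = do.call(rbind, truth))
    class(out) <- "tissue_panel_sim"
    out
  })
}
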