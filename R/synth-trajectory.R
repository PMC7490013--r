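#' Specification for synthetic differentiation trajectories
#'
#' Cells live on a one-dimensional latent differentiation axis; meta-stable
#' states are Gaussian components on that axis whose mixture weights shift
#' with age. Each cell's latent position is embedded into
#' `embedding_dim`-dimensional space along a smooth curve plus isotropic
#' Gaussian noise, emulating the principal-component input of a diffusion
#' map.
#'
#' @param n_cells Named vector: cells per age group (names = age in weeks).
#' @param state_means,state_sds Means (strictly increasing) and sds of the
#'   mixture components on the latent axis.
#' @param state_weights Matrix, one row per age (rownames matching
#'   `names(n_cells)`), one column per state; rows sum to 1.
#' @param replicates Replicates per age; cells are split evenly.
#' @param embedding_dim Dimension of the embedding (default 10).
#' @param noise_sd Isotropic noise sd in the embedding; `0` gives an exact
#'   curve.
#' @param seed Integer seed.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_cells = c("4" = 300L, "16" = 300L, "52" = 300L),
                            state_means = c(1, 4, 8),
                            state_sds = c(0.5, 0.6, 0.7),
                            state_weights = NULL,
                            replicates = 3L,
                            embedding_dim = 10L,
                            noise_sd = 0.05,
                            seed = 1L) {
  k <- length(state_means)
  if (is.null(state_weights)) {
    state_weights <- matrix(1 / k, nrow = length(n_cells), ncol = k,
                            dimnames = list(names(n_cells), NULL))
  }
  spec <- list(n_cells = n_cells, state_means = state_means,
               state_sds = state_sds, state_weights = state_weights,
               replicates = as.integer(replicates),
               embedding_dim = as.integer(embedding_dim),
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "trajectory_spec"
  validate_trajectory_spec(spec)
  spec
}

validate_trajectory_spec <- function(spec) {
  k <- length(spec$state_means)
  if (any(diff(spec$state_means) <= 0)) {
    stopf("state means must be strictly increasing")
  }
  if (length(spec$state_sds) != k || any(spec$state_sds <= 0)) {
    stopf("state sds must be positive, one per state")
  }
  w <- spec$state_weights
  if (ncol(w) != k || any(w < 0) || any(abs(rowSums(w) - 1) > 1e-8)) {
    stopf("state weights must be non-negative with rows summing to 1")
  }
  if (!all(names(spec$n_cells) %in% rownames(w))) {
    stopf("state_weights needs one row per age group")
  }
  if (spec$noise_sd < 0) stopf("noise_sd cannot be negative")
  invisible(spec)
}

#' Generate a synthetic trajectory embedding with known states
#'
#' @param spec A [trajectory_spec()].
#' @return A list of class `trajectory_sim`: `embedding` (matrix, dims x
#'   cells, suitable for [diffusion_pseudotime()]), and `truth` (data.frame
#'   per cell: `latent` position, `state`, `age`, `replicate`).
#' @export
gen_trajectory <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stopf("'spec' must be a trajectory_spec")
  validate_trajectory_spec(spec)
  with_seed(spec$seed, {
    ages <- names(spec$n_cells)
    state <- integer(0)
    age <- character(0)
    repl <- integer(0)
    for (a in ages) {
      n <- spec$n_cells[[a]]
      state <- c(state, sample.int(length(spec$state_means), n,
                                   replace = TRUE,
                                   prob = spec$state_weights[a, ]))
      age <- c(age, rep(a, n))
      repl <- c(repl, rep_len(seq_len(spec$replicates), n))
    }
    n_total <- length(state)
    latent <- rnorm(n_total, spec$state_means[state], spec$state_sds[state])
    # smooth curve through embedding space: random frequencies/phases keep
    # the curve non-self-intersecting at these scales
    freq <- runif(spec$embedding_dim, 0.05, 0.25)
    phase <- runif(spec$embedding_dim, 0, 2 * pi)
    amp <- runif(spec$embedding_dim, 0.5, 1.5)
    emb <- vapply(seq_len(spec$embedding_dim), function(d) {
      amp[d] * sin(freq[d] * latent + phase[d])
    }, numeric(n_total))
    emb <- t(emb) + rnorm(spec$embedding_dim * n_total, sd = spec$noise_sd)
    dimnames(emb) <- list(sprintf("dim%02d", seq_len(spec$embedding_dim)),
                          sprintf("cell%05d", seq_len(n_total)))
    truth <- data.frame(cell = colnames(emb), latent = latent, state = state,
                        age = as.numeric(age), replicate = repl,
                        stringsAsFactors = FALSE)
    out <- list(embedding = emb, truth = truth)
    class(out) <- "trajectory_sim"
    out
  })
}
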