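# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators and seeded algorithms funnel through this so that a fixed
# spec seed gives bit-identical output without disturbing the session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stopf("'%s' must be a single number >= %s", name, format(min))
  }
  invisible(x)
}

check_acgt <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stopf("%s contains characters outside {A,C,G,T}", what)
  }
  invisible(seq)
}

# random nucleotide strings of the given lengths, drawn from base_probs
random_nt <- function(lengths, base_probs = rep(0.25, 4)) {
  total <- sum(lengths)
  out <- character(length(lengths))
  if (total == 0L) {
    out[] <- ""
    return(out)
  }
  nt <- sample(BASES, total, replace = TRUE, prob = base_probs)
  grp <- factor(rep.int(seq_along(lengths), lengths), levels = seq_along(lengths))
  vapply(split(nt, grp), paste, character(1L), collapse = "", USE.NAMES = FALSE)
}

# geometric mean of a positive vector
geo_mean <- function(x) exp(mean(log(x)))

#' Shannon entropy of a discrete distribution
#'
#' Computes `H = -sum(f_i * log(f_i))` over the relative frequencies of the
#' input, in the requested logarithm base (bits by default). Zero-frequency
#' categories contribute nothing.
#'
#' @param x Either a vector of non-negative counts, or a character/factor
#'   vector of category labels that will be tabulated first.
#' @param base Logarithm base; `2` (the default) yields bits.
#' @return A single non-negative number.
#' @examples
#' shannon_entropy(c(1, 1, 1, 1)) # 2 bits
#' shannon_entropy(c("a", "a", "b", "c")) # 1.5 bits
#' @export
shannon_entropy <- function(x, base = 2) {
  if (is.character(x) || is.factor(x)) {
    x <- as.numeric(table(x))
  }
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stopf("'x' must be non-negative counts or a label vector")
  }
  tot <- sum(x)
  if (tot == 0) stopf("entropy of an empty distribution is undefined")
  f <- x[x > 0] / tot
  -sum(f * log(f) / log(base))
}

#' Adjust p-values for multiple testing
#'
#' Thin validating wrapper around [stats::p.adjust()] restricted to the two
#' procedures used throughout the package: Benjamini-Hochberg step-up FDR
#' control and Bonferroni family-wise control.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stopf("p-values must be numeric in [0, 1] with no missing values")
  }
  p.adjust(p, method = method)
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting form, used to compare recovered cluster or state
#' labels against ground truth. 1 means identical partitions (up to label
#' permutation), 0 is the chance level.
#'
#' @param a,b Two label vectors of equal length.
#' @return A number (at most 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
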