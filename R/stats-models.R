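#' Negative binomial test of age-dependent cluster abundance
#'
#' Models per-replicate cell counts of each group (cluster, subtype or
#' tissue) as a negative binomial function of age, with the total number of
#' cells captured per replicate as an observation weight (normalised to
#' mean 1), and tests the age terms.
#'
#' Two engines are provided. `"edgeR"` arranges the counts as a
#' groups-by-samples matrix and applies the empirical Bayes
#' quasi-likelihood F-test, sharing dispersion information across groups.
#' `"glm"` fits `MASS::glm.nb` per group and tests the age terms with a
#' likelihood-ratio chi-square (falling back to a Poisson GLM when the NB
#' fit does not converge); it additionally reports a slope standard error.
#' The engine used is labelled in the output.
#'
#' @param table data.frame with columns `group`, `age` (weeks),
#'   `replicate`, `count`, and optionally `total` (cells captured per
#'   replicate, used as weight).
#' @param terms `"linear"` (age) or `"linear+quadratic"` (age + age^2,
#'   tested jointly).
#' @param fdr Benjamini-Hochberg significance threshold (default 0.01).
#' @param engine `"edgeR"` or `"glm"`.
#' @return An object of class `abundance_test` (data.frame): per group the
#'   linear `coef` (log fold change per week, natural log), `se` (glm
#'   engine only), optional `coef_quad`, `p`, `padj`, `significant`,
#'   `method`.
#' @examples
#' tab <- expand.grid(age = c(1, 4, 16, 32, 52), replicate = 1:3)
#' tab$group <- "c1"
#' tab$count <- rnbinom(nrow(tab), mu = 50, size = 10)
#' nb_abundance_test(tab, engine = "glm")
#' @export
nb_abundance_test <- function(table, terms = c("linear", "linear+quadratic"),
                              fdr = 0.01, engine = c("edgeR", "glm")) {
  terms <- match.arg(terms)
  engine <- match.arg(engine)
  table <- check_abundance_table(table)
  groups <- unique(table$group)
  zero <- vapply(groups, function(g) {
    all(table$count[table$group == g] == 0)
  }, logical(1L))
  if (any(zero)) {
    warning(sprintf("excluding all-zero group(s): %s",
                    paste(groups[zero], collapse = ", ")), call. = FALSE)
    table <- table[!table$group %in% groups[zero], , drop = FALSE]
    groups <- groups[!zero]
  }
  if (length(groups) == 0L) stopf("no non-zero groups to test")
  if (engine == "edgeR") {
    res <- nb_abundance_edger(table, groups, terms)
  } else {
    res <- nb_abundance_glm(table, groups, terms)
  }
  res$padj <- p.adjust(res$p, method = "BH")
  res$significant <- res$padj <= fdr
  class(res) <- c("abundance_test", "data.frame")
  res
}

check_abundance_table <- function(table) {
  req <- c("group", "age", "replicate", "count")
  if (!all(req %in% names(table))) {
    stopf("abundance table needs columns %s", paste(req, collapse = ", "))
  }
  if (any(table$count < 0) || any(table$count != round(table$count))) {
    stopf("counts must be non-negative integers")
  }
  if (any(table$age <= 0)) stopf("ages must be positive")
  n_ages <- length(unique(table$age))
  if (n_ages < 3L) stopf("need >= 3 distinct ages (have %d)", n_ages)
  table
}

# sample = one (age, replicate) pair; groups become "genes" for edgeR
nb_abundance_edger <- function(table, groups, terms) {
  sample_id <- paste(table$age, table$replicate, sep = "|")
  samples <- unique(sample_id)
  y <- matrix(0, nrow = length(groups), ncol = length(samples),
              dimnames = list(groups, samples))
  y[cbind(match(table$group, groups), match(sample_id, samples))] <- table$count
  age <- table$age[match(samples, sample_id)]
  design <- if (terms == "linear") {
    model.matrix(~age)
  } else {
    model.matrix(~age + I(age^2))
  }
  w <- if ("total" %in% names(table)) {
    tot <- table$total[match(samples, sample_id)]
    tot / mean(tot)
  } else rep(1, length(samples))
  dge <- edgeR::DGEList(counts = y, lib.size = rep(1, length(samples)))
  dge <- edgeR::estimateDisp(dge, design)
  dge$weights <- matrix(w, nrow = nrow(y), ncol = length(samples),
                        byrow = TRUE)
  fit <- edgeR::glmQLFit(dge, design)
  test_coef <- if (terms == "linear") 2L else 2:3
  qlf <- edgeR::glmQLFTest(fit, coef = test_coef)
  data.frame(
    group = groups,
    coef = fit$coefficients[, 2], # natural-log change per week
    se = NA_real_,
    coef_quad = if (terms == "linear") NA_real_ else fit$coefficients[, 3],
    p = qlf$table$PValue,
    method = "edgeR_QLF",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

nb_abundance_glm <- function(table, groups, terms) {
  rows <- lapply(groups, function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    w <- if ("total" %in% names(sub)) sub$total / mean(sub$total) else NULL
    fml_full <- if (terms == "linear") count ~ age else count ~ age + I(age^2)
    fml_null <- count ~ 1
    fit_nb <- function(fml) {
      MASS::glm.nb(fml, data = cbind(sub, .w = w %||% 1), weights = .w,
                   control = stats::glm.control(maxit = 100))
    }
    out <- tryCatch({
      full <- suppressWarnings(fit_nb(fml_full))
      null <- suppressWarnings(fit_nb(fml_null))
      lr <- as.numeric(2 * (logLik(full) - logLik(null)))
      df <- length(coef(full)) - length(coef(null))
      sm <- summary(full)
      data.frame(
        group = g, coef = coef(full)[["age"]],
        se = sm$coefficients["age", "Std. Error"],
        coef_quad = if (terms == "linear") NA_real_ else
          coef(full)[["I(age^2)"]],
        p = pchisq(max(lr, 0), df = df, lower.tail = FALSE),
        method = "nb_lrt", stringsAsFactors = FALSE
      )
    }, error = function(e) NULL)
    if (is.null(out)) {
      # Poisson fallback, flagged in the method column
      full <- glm(fml_full, data = cbind(sub, .w = w %||% 1), weights = .w,
                  family = poisson())
      null <- glm(fml_null, data = cbind(sub, .w = w %||% 1), weights = .w,
                  family = poisson())
      lr <- as.numeric(2 * (logLik(full) - logLik(null)))
      df <- length(coef(full)) - length(coef(null))
      sm <- summary(full)
      out <- data.frame(
        group = g, coef = coef(full)[["age"]],
        se = sm$coefficients["age", "Std. Error"],
        coef_quad = if (terms == "linear") NA_real_ else
          coef(full)[["I(age^2)"]],
        p = pchisq(max(lr, 0), df = df, lower.tail = FALSE),
        method = "poisson_fallback", stringsAsFactors = FALSE
      )
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Poisson test of age-dependent meta-stable state abundance
#'
#' Fits, per state (optionally within lineages), a Poisson GLM of
#' per-replicate cell counts on age and tests the linear age effect;
#' p-values are Bonferroni-corrected across the states of each lineage and
#' called significant at `alpha`.
#'
#' @param state_counts data.frame with columns `state`, `age`, `replicate`,
#'   `count`, and optionally `lineage`.
#' @param alpha Adjusted significance threshold (default 0.01).
#' @return data.frame per state: `lineage`, `state`, `coef` (log change
#'   per week), `se`, `p`, `padj` (Bonferroni), `significant`.
#' @export
poisson_state_test <- function(state_counts, alpha = 0.01) {
  req <- c("state", "age", "replicate", "count")
  if (!all(req %in% names(state_counts))) {
    stopf("state counts need columns %s", paste(req, collapse = ", "))
  }
  if (!"lineage" %in% names(state_counts)) state_counts$lineage <- "all"
  out <- list()
  for (lin in unique(state_counts$lineage)) {
    sub_lin <- state_counts[state_counts$lineage == lin, , drop = FALSE]
    states <- sort(unique(sub_lin$state))
    rows <- lapply(states, function(s) {
      sub <- sub_lin[sub_lin$state == s, , drop = FALSE]
      fit <- glm(count ~ age, family = poisson(), data = sub)
      sm <- summary(fit)$coefficients
      data.frame(lineage = lin, state = s, coef = sm["age", "Estimate"],
                 se = sm["age", "Std. Error"],
                 p = sm["age", "Pr(>|z|)"], stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$padj <- pmin(res$p * length(states), 1) # Bonferroni within lineage
    out[[lin]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$significant <- res$padj <= alpha
  class(res) <- c("state_test", "data.frame")
  res
}

#' Offset-controlled test of age-dependent thymocyte selection
#'
#' Regresses the counts of each selection wave on age with a negative
#' binomial GLM, using the log of the matched parent population as a model
#' offset so that the result measures the selected fraction rather than
#' absolute cellularity. Joint rescaling of wave and parent counts
#' therefore leaves the inference unchanged. Rows with a zero parent count
#' are excluded with a warning.
#'
#' @param table data.frame with columns `group` (population/wave), `age`,
#'   `replicate`, `count` (wave cells) and `parent` (parent population
#'   cells).
#' @param fdr Benjamini-Hochberg threshold across populations (default
#'   0.01).
#' @return data.frame per group: `coef` (log change in selected fraction
#'   per week), `se`, `p`, `padj`, `significant`, `method`.
#' @export
offset_selection_test <- function(table, fdr = 0.01) {
  req <- c("group", "age", "replicate", "count", "parent")
  if (!all(req %in% names(table))) {
    stopf("selection table needs columns %s", paste(req, collapse = ", "))
  }
  bad <- table$parent <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d row(s) with zero parent counts", sum(bad)),
            call. = FALSE)
    table <- table[!bad, , drop = FALSE]
  }
  rows <- lapply(unique(table$group), function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    out <- tryCatch({
      fit <- suppressWarnings(
        MASS::glm.nb(count ~ age + offset(log(parent)), data = sub,
                     control = stats::glm.control(maxit = 100))
      )
      sm <- summary(fit)$coefficients
      data.frame(group = g, coef = sm["age", "Estimate"],
                 se = sm["age", "Std. Error"], p = sm["age", "Pr(>|z|)"],
                 method = "nb_offset", stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(out)) {
      fit <- glm(count ~ age + offset(log(parent)), family = poisson(),
                 data = sub)
      sm <- summary(fit)$coefficients
      out <- data.frame(group = g, coef = sm["age", "Estimate"],
                        se = sm["age", "Std. Error"], p = sm["age", "Pr(>|z|)"],
                        method = "poisson_fallback", stringsAsFactors = FALSE)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$padj <- p.adjust(res$p, method = "BH")
  res$significant <- res$padj <= fdr
  class(res) <- c("selection_test", "data.frame")
  res
}

#' Per-gene age trend of log-normalised expression
#'
#' Regresses each gene's log-normalised expression on `log2(age)` with the
#' log size factor as a per-cell depth covariate, using limma's moderated
#' t-statistics, and adjusts p-values with Benjamini-Hochberg.
#'
#' @param log_expr Matrix of log-normalised expression, genes x cells.
#' @param ages Per-cell age in weeks (> 0).
#' @param size_factors Per-cell size factors (> 0).
#' @param fdr Threshold recorded in the `significant` column (default
#'   0.05).
#' @return data.frame per gene: `slope` (change per doubling of age),
#'   `t`, `p`, `padj`, `significant`.
#' @export
age_expression_trend <- function(log_expr, ages, size_factors, fdr = 0.05) {
  log_expr <- as.matrix(log_expr)
  if (length(ages) != ncol(log_expr) ||
      length(size_factors) != ncol(log_expr)) {
    stopf("need one age and one size factor per cell")
  }
  if (any(ages <= 0)) stopf("ages must be positive")
  if (any(size_factors <= 0)) stopf("size factors must be positive")
  design <- cbind(Intercept = 1, log2_age = log2(ages),
                  log_sf = log(size_factors))
  if (sd(design[, "log_sf"]) == 0) {
    design <- design[, c("Intercept", "log2_age")] # constant depth: drop
  }
  fit <- limma::lmFit(log_expr, design)
  fit <- limma::eBayes(fit)
  p <- fit$p.value[, "log2_age"]
  slope <- fit$coefficients[, "log2_age"]
  # genes with no residual variance carry no evidence
  p[!is.finite(p)] <- 1
  res <- data.frame(gene = rownames(log_expr), slope = slope,
                    t = fit$t[, "log2_age"], p = p,
                    padj = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  res$significant <- res$padj <= fdr
  class(res) <- c("expression_trend", "data.frame")
  res
}
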