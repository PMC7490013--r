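ages5 <- c(1, 4, 16, 32, 52)

make_abundance <- function(slope, groups = "g1", mu0 = 200, size = 10,
                           n_rep = 5, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(age = ages5, replicate = seq_len(n_rep), group = groups,
                     stringsAsFactors = FALSE)
  tab$count <- rnbinom(nrow(tab), mu = mu0 * exp(slope * tab$age), size = size)
  tab$total <- rpois(nrow(tab), 5000)
  tab
}

test_that("constant abundance is not called age dependent", {
  tab <- make_abundance(slope = 0, seed = 80)
  for (eng in c("glm", "edgeR")) {
    res <- nb_abundance_test(tab, engine = eng)
    expect_false(res$significant)
    expect_lt(abs(res$coef), 0.02)
  }
})

test_that("a planted decline is recovered with a calibrated slope", {
  tab <- make_abundance(slope = -0.1, seed = 81)
  res <- nb_abundance_test(tab, engine = "glm")
  expect_true(res$significant)
  expect_lt(abs(res$coef + 0.1), 2 * res$se)
  expect_equal(res$method, "nb_lrt")
  # the quasi-likelihood engine agrees on the call and the coefficient
  res2 <- nb_abundance_test(tab, engine = "edgeR")
  expect_true(res2$significant)
  expect_equal(res2$coef, res$coef, tolerance = 0.05)
})

test_that("one affected group among nulls is the only discovery", {
  set.seed(82)
  tab <- expand.grid(age = ages5, replicate = 1:5,
                     group = paste0("g", 1:10), stringsAsFactors = FALSE)
  mu <- ifelse(tab$group == "g1", 200 * exp(-0.1 * tab$age), 200)
  tab$count <- rnbinom(nrow(tab), mu = mu, size = 10)
  tab$total <- rpois(nrow(tab), 5000)
  res <- nb_abundance_test(tab, engine = "edgeR", fdr = 0.01)
  expect_true(res$significant[res$group == "g1"])
  expect_false(any(res$significant[res$group != "g1"]))
})

test_that("quadratic terms are fitted and tested jointly on request", {
  set.seed(83)
  tab <- expand.grid(age = ages5, replicate = 1:5, group = "g1",
                     stringsAsFactors = FALSE)
  mu <- 400 * exp(-0.15 * tab$age + 0.002 * tab$age^2)
  tab$count <- rnbinom(nrow(tab), mu = mu, size = 20)
  res <- nb_abundance_test(tab, terms = "linear+quadratic", engine = "glm")
  expect_false(is.na(res$coef_quad))
  expect_true(res$significant)
})

test_that("abundance table validation and all-zero exclusion work", {
  tab <- make_abundance(0, seed = 84)
  expect_error(nb_abundance_test(tab[tab$age < 5, ]), "3 distinct ages")
  tab$count[1] <- -1
  expect_error(nb_abundance_test(tab), "non-negative")
  tab2 <- make_abundance(0, groups = c("g1", "dead"), seed = 85)
  tab2$count[tab2$group == "dead"] <- 0L
  expect_warning(res <- nb_abundance_test(tab2, engine = "glm"), "all-zero")
  expect_equal(res$group, "g1")
})

test_that("the Poisson state test flags planted shifts and only those", {
  set.seed(86)
  tab <- expand.grid(state = 1:3, age = ages5, replicate = 1:4,
                     stringsAsFactors = FALSE)
  lam <- with(tab, ifelse(state == 1, 20 * exp(0.05 * age),
                          ifelse(state == 3, 60 * exp(-0.05 * age), 40)))
  tab$count <- rpois(nrow(tab), lam)
  res <- poisson_state_test(tab, alpha = 0.01)
  expect_true(res$significant[res$state == 1])
  expect_true(res$significant[res$state == 3])
  expect_false(res$significant[res$state == 2])
  expect_gt(res$coef[res$state == 1], 0)
  expect_lt(res$coef[res$state == 3], 0)
  # flat counts: nothing flagged
  tab$count <- rep(30L, nrow(tab))
  expect_false(any(poisson_state_test(tab)$significant))
  # single state: Bonferroni leaves the p-value untouched
  one <- tab[tab$state == 1, ]
  res1 <- poisson_state_test(one)
  expect_equal(res1$padj, res1$p)
})

test_that("selection tests measure the fraction, not the cellularity", {
  set.seed(87)
  tab <- expand.grid(age = ages5, replicate = 1:4, group = "wave1",
                     stringsAsFactors = FALSE)
  tab$parent <- rpois(nrow(tab), 8000)
  # constant 10% selection at every age: no age effect
  tab$count <- rbinom(nrow(tab), tab$parent, 0.10)
  res <- nb_abundance_test # silence lint for unused
  r0 <- offset_selection_test(tab)
  expect_false(r0$significant)
  expect_lt(abs(r0$coef), 0.02)
  # selected fraction halving every 10 weeks: log(2)/10 per week decline
  tab$count <- rbinom(nrow(tab), tab$parent, 0.2 * 2^(-tab$age / 10))
  r1 <- offset_selection_test(tab)
  expect_true(r1$significant)
  expect_lt(abs(r1$coef + log(2) / 10), 2 * r1$se)
  # joint rescaling of wave and parent barely moves the inference
  tab2 <- tab
  tab2$count <- tab2$count * 4L
  tab2$parent <- tab2$parent * 4L
  r2 <- offset_selection_test(tab2)
  expect_equal(r2$coef, r1$coef, tolerance = 0.01)
  expect_equal(r2$significant, r1$significant)
  # zero parents are excluded with a warning
  tab$parent[1] <- 0
  expect_warning(offset_selection_test(tab), "zero parent")
})

test_that("expression trends recover exact and null genes", {
  set.seed(88)
  n_cells <- 120
  ages <- rep(c(1, 4, 16, 52), each = 30)
  sf <- rlnorm(n_cells, 0, 0.2)
  exact <- log2(ages)
  null_genes <- matrix(rnorm(1000 * n_cells), nrow = 1000)
  expr <- rbind(exact = exact, constant = rep(3, n_cells), null_genes)
  rownames(expr) <- c("exact", "constant", sprintf("null%04d", 1:1000))
  res <- age_expression_trend(expr, ages, sf)
  expect_equal(res$slope[res$gene == "exact"], 1, tolerance = 1e-6)
  expect_lt(res$p[res$gene == "exact"], 1e-10)
  expect_equal(res$slope[res$gene == "constant"], 0)
  expect_gt(res$p[res$gene == "constant"], 0.99)
  # null genes keep the nominal type-I rate
  null_p <- res$p[startsWith(res$gene, "null")]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.02)
  expect_error(age_expression_trend(expr, ages[-1], sf), "one age")
  expect_error(age_expression_trend(expr, ages * 0, sf), "positive")
})

test_that("p-value adjustment matches the hand-computed step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(rep(1, 5), "BH"), rep(1, 5))
  # monotone in the input ranks
  p <- c(0.001, 0.01, 0.2, 0.8)
  expect_true(all(diff(adjust_pvalues(p, "BH")) >= 0))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})
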