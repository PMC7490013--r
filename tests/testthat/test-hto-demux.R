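test_that("background threshold fitting matches analytic quantiles", {
  # large clean NB sample: q within one count of the analytic 99th quantile
  set.seed(50)
  bg <- rnbinom(1e5, mu = 5, size = 2)
  fit <- fit_background_threshold(bg, quantile = 0.99)
  expect_true(startsWith(fit$method, "nb"))
  expect_lte(abs(fit$q - qnbinom(0.99, mu = 5, size = 2)), 1)
  # constant background: degenerate distribution, q equals the constant
  fitc <- fit_background_threshold(rep(7L, 50))
  expect_equal(fitc$method, "degenerate")
  expect_equal(fitc$q, 7)
  # underdispersed background: Poisson fallback
  set.seed(51)
  under <- rbinom(500, size = 10, prob = 0.5)
  fitp <- fit_background_threshold(under)
  expect_equal(fitp$method, "poisson")
  # quantile 0 admits everything
  expect_equal(fit_background_threshold(bg, quantile = 0)$q, 0)
  expect_error(fit_background_threshold(rep(1L, 5)), ">= 20")
  # raising the quantile never lowers the threshold
  q_hi <- fit_background_threshold(bg, quantile = 0.999)$q
  expect_gte(q_hi, fit$q)
})

test_that("demultiplexing partitions every barcode into one call", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 3, n_singlets = 60,
                                     n_doublets = 15, n_empty = 15, seed = 52))
  dmx <- hto_demux(sim$counts, seed = 1)
  calls <- dmx$calls
  expect_equal(nrow(calls), ncol(sim$counts))
  tab <- table(factor(calls$call, c("Singlet", "Multiplet", "Dropout")))
  expect_equal(sum(tab), ncol(sim$counts))
  # calls and assignment counts are consistent by construction
  expect_true(all((calls$call == "Singlet") == (calls$n_assigned == 1)))
  expect_true(all((calls$call == "Multiplet") == (calls$n_assigned > 1)))
  expect_true(all((calls$call == "Dropout") == (calls$n_assigned == 0)))
  # all-zero barcodes never clear a positive threshold
  zero_bc <- colnames(sim$counts)[colSums(sim$counts) == 0]
  if (length(zero_bc)) {
    expect_true(all(calls$call[calls$barcode %in% zero_bc] == "Dropout"))
  }
})

test_that("synthetic mixtures are demultiplexed against generator truth", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 6, n_singlets = 150,
                                     n_doublets = 90, n_empty = 45,
                                     signal_mean = 500, background_mean = 5,
                                     seed = 53))
  dmx <- hto_demux(sim$counts, seed = 2)
  truth <- sim$truth
  calls <- dmx$calls
  sing <- truth$type == "singlet"
  recall <- mean(calls$call[sing] == "Singlet" &
                   calls$assigned[sing] == truth$hto1[sing])
  expect_gte(recall, 0.95)
  doub <- truth$type == "doublet"
  expect_gte(mean(calls$call[doub] == "Multiplet"), 0.85)
  empty <- truth$type == "empty"
  expect_gte(mean(calls$call[empty] == "Dropout"), 0.9)
})

test_that("two clean hashtags are recovered almost perfectly", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 150,
                                     n_doublets = 0, n_empty = 20,
                                     signal_mean = 500, background_mean = 1,
                                     seed = 54))
  dmx <- hto_demux(sim$counts, seed = 3)
  truth <- sim$truth
  sing <- truth$type == "singlet"
  recall <- mean(dmx$calls$call[sing] == "Singlet" &
                   dmx$calls$assigned[sing] == truth$hto1[sing])
  # a 99th-quantile background threshold leaves P(bg >= q) ~ 1.6% of
  # singlets with an above-threshold count on the *other* hashtag
  # (NB(1, 1): 1 - CDF(q - 1) = 0.0156 at q = 6), so near-perfect but not
  # perfect recovery is the exact expectation here
  expect_gte(recall, 0.97)
  expect_true(all(dmx$calls$call[sing] %in% c("Singlet", "Multiplet")))
})

test_that("signal indistinguishable from background still yields a full call set", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 60,
                                     n_doublets = 10, n_empty = 10,
                                     signal_mean = 5, signal_size = 1,
                                     background_mean = 5, seed = 55))
  dmx <- hto_demux(sim$counts, seed = 4)
  expect_equal(nrow(dmx$calls), ncol(sim$counts))
  expect_true(all(dmx$calls$call %in% c("Singlet", "Multiplet", "Dropout")))
})

test_that("quantile = 0 assigns every hashtag to every barcode", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 30,
                                     n_doublets = 0, n_empty = 0, seed = 56))
  dmx <- hto_demux(sim$counts, quantile = 0, seed = 5)
  expect_true(all(dmx$calls$call == "Multiplet"))
  expect_true(all(dmx$calls$n_assigned == 2))
})

test_that("raising a barcode's count never revokes its assignment", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 100,
                                     n_doublets = 10, n_empty = 10, seed = 57))
  dmx <- hto_demux(sim$counts, seed = 6)
  q1 <- dmx$thresholds$q[dmx$thresholds$hto == "HTO1"]
  assigned_before <- sim$counts["HTO1", ] >= q1
  boosted <- sim$counts
  boosted["HTO1", ] <- boosted["HTO1", ] + 10L
  # same thresholds, higher counts: assignment set can only grow
  expect_true(all(boosted["HTO1", assigned_before] >= q1))
})

test_that("demux validates its inputs", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 30,
                                     n_doublets = 0, n_empty = 0, seed = 58))
  expect_error(hto_demux(sim$counts[1, , drop = FALSE]), ">= 2 HTOs")
  expect_error(hto_demux(sim$counts[, 1:10]), "barcodes per HTO")
  expect_error(hto_demux(sim$counts, expected_htos = c("HTO1", "HTO9")),
               "absent")
})
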