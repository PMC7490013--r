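test_that("productivity scan matches hand-constructed open reading frames", {
  # in-frame stop before the end -> unproductive
  expect_false(is_productive("ATGAAATAAGGGGGG", "ATGAAA"))
  # stop-free frame tiling the sequence -> productive
  expect_true(is_productive("ATGAAACCCGGGAAA", "ATGAAA"))
  # frame must start at an ATG inside the V portion
  expect_false(is_productive("CCCATGAAAGGG", "CCC"))
  # length from ATG must be a codon multiple
  expect_false(is_productive("ATGAAAC", "ATGAAA"))
  expect_error(is_productive("ATGNNN", "ATG"), "A,C,G,T")
})

test_that("productivity scan agrees with a Biostrings translation oracle", {
  set.seed(401)
  n_checked <- 0
  for (i in 1:300) {
    v_len <- sample(20:40, 1)
    tail_len <- sample(c(60, 61, 62), 1)
    seqs <- paste(sample(c("A", "C", "G", "T"), v_len + tail_len,
                         replace = TRUE), collapse = "")
    # plant an ATG in about half the cases so both outcomes are exercised
    if (i %% 2 == 0) {
      pos <- sample(v_len - 2, 1)
      substr(seqs, pos, pos + 2) <- "ATG"
    }
    got <- is_productive(seqs, substr(seqs, 1, v_len))
    want <- oracle_productive(seqs, v_len)
    expect_identical(got, want)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("zero-insertion rearrangement is the exact segment concatenation", {
  loc <- productive_locus()
  set.seed(1)
  att_b <- rearrange_chain("beta", loc, attempt_index = 1, lambda = 0)
  expect_equal(att_b$sequence,
               paste0("ATGGCCGCCGCA", "GCCGCA", "GCAGCTGCA", "GCAGCTGCA"))
  expect_true(att_b$productive)
  expect_equal(att_b$ins1 + att_b$ins2, 0)
  att_a <- rearrange_chain("alpha", loc, lambda = 0)
  expect_equal(att_a$sequence, paste0("ATGGCCGCCGCA", "GCAGCTGCA", "GCAGCTGCA"))
  # cassette 2 uses the cassette-2 J and C segments
  att_b2 <- rearrange_chain("beta", loc, attempt_index = 2, lambda = 0)
  expect_equal(att_b2$j, "TRBJ2-1")
  expect_equal(att_b2$c, "TRBC2")
})

test_that("insertion lengths follow the Poisson(lambda) model", {
  loc <- gen_germline_locus(locus_spec(seed = 2))
  rep <- simulate_repertoire(loc, n = 5000, seed = 7)
  beta <- rep$attempts[rep$attempts$chain == "beta", ]
  alpha <- rep$attempts[rep$attempts$chain == "alpha", ]
  # alpha: one junction, mean 4; beta: two junctions, mean 8
  se_b <- sqrt(8 / nrow(beta))
  expect_lt(abs(mean(beta$ins1 + beta$ins2) - 8), 4 * se_b)
  se_a <- sqrt(4 / nrow(alpha))
  expect_lt(abs(mean(alpha$ins1) - 4), 4 * se_a)
  expect_true(all(is.na(alpha$ins2)))
})

test_that("thymocytes follow the attempt program and allelic exclusion", {
  # ATG-free locus: four beta attempts, no alpha attempts, no pair
  set.seed(3)
  thy <- simulate_thymocyte(atg_free_locus())
  expect_false(thy$productive_pair)
  expect_equal(nrow(thy$attempts), 4)
  expect_true(all(thy$attempts$chain == "beta"))
  expect_equal(thy$attempts$cassette, c("1", "2", "1", "2"))
  expect_equal(thy$attempts$allele, c(1L, 1L, 2L, 2L))
  # fully productive locus: one beta then one alpha attempt
  set.seed(4)
  thy2 <- simulate_thymocyte(productive_locus(), lambda = 0)
  expect_true(thy2$productive_pair)
  expect_equal(nrow(thy2$attempts), 2)
  expect_equal(sort(unique(thy2$attempts$chain)), c("alpha", "beta"))
})

test_that("beta success rate matches the closed form over four attempts", {
  loc <- gen_germline_locus(locus_spec(seed = 5))
  rep <- simulate_repertoire(loc, n = 30000, seed = 13)
  att <- rep$attempts[rep$attempts$chain == "beta", ]
  p1 <- mean(att$productive[att$cassette == "1"])
  p2 <- mean(att$productive[att$cassette == "2"])
  predicted <- 1 - (1 - p1)^2 * (1 - p2)^2
  observed <- mean(rep$thymocytes$beta_productive)
  se <- sqrt(observed * (1 - observed) / nrow(rep$thymocytes))
  expect_lt(abs(observed - predicted), 3 * se)
  # alpha success given beta follows the two-attempt closed form
  aatt <- rep$attempts[rep$attempts$chain == "alpha", ]
  pa <- mean(aatt$productive)
  reached <- rep$thymocytes$beta_productive
  obs_a <- mean(rep$thymocytes$alpha_productive[reached])
  pred_a <- 1 - (1 - pa)^2
  se_a <- sqrt(obs_a * (1 - obs_a) / sum(reached))
  expect_lt(abs(obs_a - pred_a), 3 * se_a)
})

test_that("repertoire modes, determinism and guards behave", {
  loc <- gen_germline_locus(locus_spec(seed = 6))
  expect_error(simulate_repertoire(loc, n = 0), "n")
  r1 <- simulate_repertoire(loc, n = 500, seed = 42)
  r2 <- simulate_repertoire(loc, n = 500, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$n_attempted, 500)
  expect_true(r1$n_attempted >= sum(r1$thymocytes$productive_pair))
  # productive mode returns exactly n productive pairs
  rp <- simulate_repertoire(loc, n = 50, mode = "productive", seed = 9)
  expect_equal(sum(rp$thymocytes$productive_pair), 50)
  expect_true(rp$n_attempted >= 50)
  # and refuses to run forever on a hopeless locus
  expect_error(
    simulate_repertoire(atg_free_locus(), n = 5, mode = "productive",
                        seed = 1, max_attempts = 200),
    "max_attempts"
  )
})

test_that("clonotypes translate the junction window in the productive frame", {
  loc <- productive_locus()
  set.seed(10)
  att <- rearrange_chain("alpha", loc, lambda = 0)
  # window: last 9 nt of V + first 9 nt of J, all alanine codons
  expect_equal(clonotype(att, flank_nt = 9), "AAAAAA")
  att_b <- rearrange_chain("beta", loc, attempt_index = 1, lambda = 0)
  # window additionally spans the 6-nt D segment
  expect_equal(clonotype(att_b, flank_nt = 9), "AAAAAAAA")
  expect_error(clonotype(rearrange_chain("beta", atg_free_locus())),
               "productive")
})

test_that("clonotypes agree with an independent translate-and-slice oracle", {
  loc <- gen_germline_locus(locus_spec(seed = 12))
  set.seed(402)
  checked <- 0
  while (checked < 50) {
    att <- rearrange_chain(sample(c("alpha", "beta"), 1), loc,
                           attempt_index = sample(1:2, 1))
    if (!att$productive) next
    got <- clonotype(att, flank_nt = 9)
    # oracle: translate the whole ORF with Biostrings, then slice the
    # amino acids whose codons overlap the junction window
    orf <- att$orf_start
    n <- nchar(att$sequence)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(att$sequence, orf, orf + 3 * ((n - orf + 1) %/% 3) - 1)
    ), no.init.codon = TRUE))
    mid <- att$ins1
    if (!is.na(att$ins2)) mid <- mid + nchar(att$d_seq) + att$ins2
    a <- max(att$v_len - 8, orf)
    b <- min(att$v_len + mid + 9, n)
    i1 <- max(1, (a - orf) %/% 3 + 1)
    i2 <- min(nchar(aa), (b - orf) %/% 3 + 1)
    expect_equal(got, substr(aa, i1, i2))
    checked <- checked + 1
  }
  # identical segments and insertions give identical clonotypes
  set.seed(11)
  a1 <- rearrange_chain("alpha", productive_locus(), lambda = 0)
  a2 <- rearrange_chain("alpha", productive_locus(), lambda = 0)
  expect_identical(clonotype(a1), clonotype(a2))
})

test_that("Shannon entropy matches hand-computed values and invariances", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_entropy(c(5)), 0)
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.5)
  expect_equal(shannon_entropy(c("x", "x", "y", "z")), 1.5)
  # relabelling and order invariance
  expect_equal(shannon_entropy(c(1, 2, 3)), shannon_entropy(c(3, 1, 2)))
  expect_error(shannon_entropy(numeric(0)), "undefined")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("saturation statistics subsample without replacement and sum to one", {
  loc <- gen_germline_locus(locus_spec(seed = 14))
  rep <- simulate_repertoire(loc, n = 4000, seed = 15)
  n_prod <- sum(rep$thymocytes$productive_pair)
  expect_error(saturation_stats(rep, sizes = n_prod + 1), "exceeds")
  sat <- saturation_stats(rep, sizes = c(10, 50), n_seeds = 3, seed = 2)
  # usage proportions sum to 1 within every (size, seed, chain, segtype)
  sums <- aggregate(proportion ~ size + seed + chain + segtype,
                    data = sat$usage, FUN = sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-12))
  expect_equal(nrow(sat$entropy), 2 * 3 * 2)
  expect_true(all(sat$entropy$entropy >= 0))
  # entropy grows with subsample size in expectation
  mean_h <- tapply(sat$entropy$entropy, sat$entropy$size, mean)
  expect_true(mean_h["50"] > mean_h["10"])
})
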