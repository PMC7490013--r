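test_that("germline locus generation is deterministic and respects invariants", {
  spec <- locus_spec(seed = 11)
  loc1 <- gen_germline_locus(spec)
  loc2 <- gen_germline_locus(spec)
  expect_identical(loc1, loc2)
  expect_false(anyDuplicated(loc1$name) > 0)
  expect_true(all(grepl("^[ACGT]+$", loc1$sequence)))
  beta_j <- loc1[loc1$chain == "beta" & loc1$segtype == "J", ]
  expect_setequal(unique(beta_j$cassette), c("1", "2"))
  expect_true(all(loc1$cassette[loc1$chain == "alpha"] == "none"))
  # FASTA round trip is lossless
  path <- tempfile(fileext = ".fasta")
  write_locus_fasta(loc1, path)
  expect_equal(read_locus_fasta(path), loc1)
  # byte-identical FASTA for the same seed
  path2 <- tempfile(fileext = ".fasta")
  write_locus_fasta(gen_germline_locus(spec), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("atg_frac steers which V segments can seed an open reading frame", {
  loc <- gen_germline_locus(locus_spec(atg_frac = 0, seed = 3))
  v <- loc$sequence[loc$segtype == "V"]
  expect_false(any(grepl("ATG", v, fixed = TRUE)))
  # and with atg_frac = 0 nothing can ever be productive
  rep <- simulate_repertoire(loc, n = 50, seed = 1)
  expect_equal(sum(rep$thymocytes$beta_productive), 0)
  loc1 <- gen_germline_locus(locus_spec(atg_frac = 1, atg_offset = 4, seed = 3))
  v1 <- loc1$sequence[loc1$segtype == "V"]
  expect_true(all(substr(v1, 4, 6) == "ATG"))
})

test_that("locus_spec rejects invalid configurations", {
  expect_error(locus_spec(n_j = c(alpha = 5, beta = 1)), "cassette")
  expect_error(locus_spec(n_d = 0), "D segment")
  expect_error(locus_spec(atg_offset = 100), "ATG")
  expect_error(locus_spec(len_v = c(50, 40)), "len_v")
})

test_that("synthetic counts carry truth separately and honour composition", {
  props <- rbind("4" = c(0.8, 0.1, 0.1), "52" = c(0.1, 0.1, 0.8))
  spec <- sc_count_spec(
    n_genes = 300, n_clusters = 3, markers_per_cluster = 20,
    cells = data.frame(age = rep(c(4, 52), each = 2),
                       replicate = rep(1:2, 2), n_cells = 200),
    cluster_props = props, seed = 5
  )
  sim <- gen_sc_counts(spec)
  expect_s3_class(sim$matrix, "cell_matrix")
  counts <- sim$matrix$counts
  expect_true(all(counts@x >= 0))
  expect_true(all(counts@x == round(counts@x)))
  # truth labels live outside the matrix object
  expect_false("cluster" %in% names(sim$matrix$cell_meta))
  expect_length(sim$truth$cluster, ncol(counts))
  # composition follows the age map (multinomial tolerance)
  young <- sim$matrix$cell_meta$age == 4
  expect_gt(mean(sim$truth$cluster[young] == 1), 0.7)
  expect_lt(mean(sim$truth$cluster[!young] == 1), 0.2)
  # determinism
  expect_identical(gen_sc_counts(spec)$matrix$counts, counts)
})

test_that("full dropout yields an all-zero matrix flagged degenerate", {
  spec <- sc_count_spec(n_genes = 100, n_clusters = 2,
                        markers_per_cluster = 5,
                        cells = data.frame(age = 4, replicate = 1,
                                           n_cells = 20),
                        dropout = 1, seed = 2)
  expect_warning(sim <- gen_sc_counts(spec), "degenerate")
  expect_equal(sum(sim$matrix$counts), 0)
  expect_true(sim$truth$degenerate)
})

test_that("sc_count_spec validates proportions and group sizes", {
  expect_error(
    sc_count_spec(cells = data.frame(age = 4, replicate = 1, n_cells = 0)),
    "at least one cell"
  )
  bad <- rbind("4" = c(0.5, 0.6))
  expect_error(
    sc_count_spec(n_clusters = 2, cluster_props = bad,
                  cells = data.frame(age = 4, replicate = 1, n_cells = 5)),
    "sum to 1"
  )
})

test_that("HTO mixtures encode truth and degenerate cases behave", {
  sim <- gen_hto_counts(hto_mix_spec(n_htos = 3, n_singlets = 40,
                                     n_doublets = 10, n_empty = 5, seed = 9))
  expect_equal(dim(sim$counts), c(3, 135))
  expect_equal(sum(sim$truth$type == "doublet"), 10)
  doublets <- sim$truth[sim$truth$type == "doublet", ]
  expect_true(all(doublets$hto1 != doublets$hto2))
  expect_error(hto_mix_spec(signal_mean = 0), "positive")
  # empty-only mixture: all barcodes are background
  empt <- gen_hto_counts(hto_mix_spec(n_htos = 2, n_singlets = 0,
                                      n_doublets = 0, n_empty = 50, seed = 1))
  expect_true(all(empt$truth$type == "empty"))
})

test_that("tissue panels contain the advertised tau structure", {
  sim <- gen_tissue_panel(n_single = 10, n_uniform = 10, n_graded = 10,
                          n_random = 10, n_tissues = 27, seed = 4)
  expect_equal(dim(sim$panel), c(40, 27))
  expect_true(all(sim$panel >= 0))
  single <- sim$panel[sim$truth$class == "single", , drop = FALSE]
  expect_true(all(rowSums(single > 0) == 1))
  uniform <- sim$panel[sim$truth$class == "uniform", , drop = FALSE]
  expect_true(all(apply(uniform, 1, function(r) diff(range(r))) == 0))
})

test_that("trajectory generator validates weights and embeds the latent axis", {
  expect_error(trajectory_spec(state_means = c(3, 1, 8)), "increasing")
  w <- rbind("4" = c(0.9, 0.2))
  expect_error(
    trajectory_spec(n_cells = c("4" = 10), state_means = c(1, 5),
                    state_sds = c(1, 1), state_weights = w),
    "summing to 1"
  )
  sim <- gen_trajectory(trajectory_spec(seed = 8))
  expect_equal(ncol(sim$embedding), nrow(sim$truth))
  expect_equal(sort(unique(sim$truth$state)), 1:3)
})
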