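test_that("make_genome tiles chromosomes and rank-rescales timing to [0,1]", {
  cfg <- sim_config(seed = 3)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 100)
  expect_equal(nrow(g$bins), 100)
  expect_equal(min(g$bins$timing), 0)
  expect_equal(max(g$bins$timing), 1)
  # bins tile without gaps or overlaps
  expect_equal(g$bins$start[-1], g$bins$end[-100])
  expect_true(all(g$bins$end - g$bins$start == g$bin_size))
  expect_true(all(g$bins$copy >= 1))
  # genes lie fully within their chromosome span
  expect_true(all(g$genes$end <= g$chrom_sizes[g$genes$chrom]))
  expect_true(all(g$genes$start >= 0))
})

test_that("make_genome is deterministic given a seed and rejects bad dims", {
  cfg <- sim_config(seed = 5)
  g1 <- make_genome(cfg, n_chrom = 2, bins_per_chrom = 50)
  g2 <- make_genome(cfg, n_chrom = 2, bins_per_chrom = 50)
  expect_identical(g1, g2)
  expect_error(make_genome(cfg, n_chrom = 0, bins_per_chrom = 50))
  expect_error(make_genome(cfg, n_chrom = 1, bins_per_chrom = 5),
               "rt_smoothness")
})

test_that("rt_smoothness = 1 yields an unautocorrelated timing program", {
  cfg <- sim_config(seed = 7, rt_smoothness = 1)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 2500, n_genes = 0)
  t <- g$bins$timing
  r <- cor(t[-1], t[-length(t)])
  expect_lt(abs(r), 0.1)
  # smoothing induces strong positive autocorrelation by comparison
  gs <- make_genome(sim_config(seed = 7, rt_smoothness = 20),
                    n_chrom = 1, bins_per_chrom = 2500, n_genes = 0)
  ts <- gs$bins$timing
  expect_gt(cor(ts[-1], ts[-length(ts)]), 0.8)
})

test_that("make_genome places CNV segments with the requested copy", {
  cfg <- sim_config(seed = 2)
  cnv <- data.frame(chrom = "chr1", start_bin = 11, end_bin = 30, copy = 3)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 100, cnv = cnv)
  expect_equal(g$bins$copy[11:30], rep(3L, 20))
  expect_equal(g$bins$copy[-(11:30)], rep(2L, 80))
})

test_that("simulate_cell replicates exactly the earliest fraction when noiseless", {
  g <- make_genome(sim_config(seed = 1), n_chrom = 1, bins_per_chrom = 200,
                   n_genes = 0)
  cell <- simulate_cell(g, "S3", s_fraction = 0.5, flip_noise = 0, seed = 1)
  expect_equal(mean(cell$states_true), 0.5, tolerance = 1 / 200)
  # the replicated set is exactly the top half of timing values
  top <- order(g$bins$timing, decreasing = TRUE)[1:100]
  expect_setequal(which(cell$states_true == 1), top)

  expect_equal(simulate_cell(g, "S5", s_fraction = 1)$states_true,
               rep(1L, 200))
  expect_equal(simulate_cell(g, "G1")$states_true, rep(0L, 200))
  expect_equal(simulate_cell(g, "G2")$states_true, rep(1L, 200))
  expect_error(simulate_cell(g, "S9"), "unknown gate")
})

test_that("flip noise preserves the expected replicated fraction and agreement", {
  g <- make_genome(sim_config(seed = 4), n_chrom = 1, bins_per_chrom = 500,
                   n_genes = 0)
  clean <- simulate_cell(g, "S3", s_fraction = 0.5, flip_noise = 0)
  set.seed(99)
  fracs <- agree <- numeric(120)
  for (i in seq_len(120)) {
    noisy <- simulate_cell(g, "S3", s_fraction = 0.5, flip_noise = 0.1)
    fracs[i] <- mean(noisy$states_true)
    agree[i] <- mean(noisy$states_true == clean$states_true)
  }
  # E[frac] = 0.5(1-eps) + 0.5 eps = 0.5; E[agreement] = 1 - eps = 0.9
  n <- 120 * 500
  expect_equal(mean(fracs), 0.5, tolerance = 3 * sqrt(0.25 / n))
  expect_equal(mean(agree), 0.9, tolerance = 3 * sqrt(0.09 / n))
})

test_that("simulate_counts follows the Poisson copy-replication mean model", {
  g <- make_genome(sim_config(seed = 6), n_chrom = 1, bins_per_chrom = 1500,
                   n_genes = 0)
  g1 <- simulate_cell(g, "G1")
  g2 <- simulate_cell(g, "G2")
  c1 <- simulate_counts(g, g1, depth = 100, seed = 21)
  c2 <- simulate_counts(g, g2, depth = 100, seed = 22)
  # unreplicated diploid bins have mean depth (3 sigma / sqrt(n) band)
  expect_equal(mean(c1), 100, tolerance = 3 * sqrt(100 / 1500) / 100)
  # uniform doubling in G2
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.03)
  expect_error(simulate_counts(g, g1, depth = 0), "depth")
})

test_that("expression on-probability follows the logistic link in RT", {
  cfg <- sim_config(seed = 8, expr_intercept = 0, expr_slope = 4)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 100, n_genes = 6000)
  rt <- rep(0.5, 6000)
  m <- simulate_expression(g, rt, cfg, cell_ids = "c1", seed = 31)
  expect_s3_class(m, "expr_matrix")
  expect_equal(m$unit, "FPKM")
  # truncated emissions make the expressed call equal the latent on state,
  # so the empirical on-rate estimates sigmoid(0 + 4 * 0.5) = 0.8808
  on_rate <- mean(expressed_call(m))
  expect_equal(on_rate, plogis(2), tolerance = 3 * sqrt(0.105 / 6000) / plogis(2))
  expect_error(simulate_expression(g, rt[-1], cfg), "one RT value per gene")
})

test_that("b = 0 makes expression independent of RT", {
  cfg <- sim_config(seed = 9, expr_slope = 0)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 100, n_genes = 4000)
  rt <- gene_truth_rt(g)
  m <- simulate_expression(g, rt, cfg, cell_ids = c("c1", "c2"), seed = 5)
  on <- rowMeans(expressed_call(m))
  expect_lt(abs(cor(on, rt)), 0.05)
})

test_that("fixtures round-trip losslessly and are byte-identical per seed", {
  exp <- small_experiment()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(exp, d1)
  fx <- read_fixture(d1)
  expect_equal(unname(fx$counts), unname(exp$counts))
  expect_equal(colnames(fx$counts), colnames(exp$counts))
  expect_equal(fx$meta$cell_id, exp$meta$cell_id)
  expect_equal(fx$meta$gate, exp$meta$gate)
  expect_equal(fx$expression$values, exp$expression$values, tolerance = 1e-8)
  expect_equal(fx$expression$unit, "FPKM")
  expect_equal(nrow(fx$states_true), nrow(exp$genome$bins))
  expect_equal(fx$manifest$seed, exp$config$seed)

  # identical config + seed => byte-identical fixture files
  exp2 <- simulate_experiment(exp$config, n_chrom = 1, bins_per_chrom = 400,
                              n_genes = 600)
  write_fixture(exp2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
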