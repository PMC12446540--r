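test_that("G1 baseline recovers diploid copy and simulated CNV", {
  cfg <- sim_config(seed = 14, flip_noise = 0)
  cnv <- data.frame(chrom = "chr1", start_bin = 101, end_bin = 140, copy = 3)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 600, n_genes = 0,
                   cnv = cnv)
  set.seed(1)
  counts <- sapply(1:13, function(i)
    simulate_counts(g, simulate_cell(g, "G1"), depth = 100))
  colnames(counts) <- paste0("G1_", 1:13)
  wcm <- wcm_from_bins(g, counts)
  bl <- g1_baseline(wcm, colnames(counts))
  expect_true(all(abs(bl$copy[-(101:140)] - 2) < 0.2))       # +-10%
  expect_true(mean(bl$copy[101:140]) > 2.7 &&
                mean(bl$copy[101:140]) < 3.3)                # CNV recovered
  expect_error(g1_baseline(wcm, character(0)), "at least one G1",
               class = "screpli_config_error")
})

test_that("normalize_cell is self-consistent, scale-invariant and flags zeros", {
  exp <- small_experiment()
  wcm <- wcm_from_bins(exp$genome, exp$counts)
  g1 <- exp$meta$cell_id[exp$meta$gate == "G1"]
  bl <- g1_baseline(wcm, g1)

  # a cell equal to the baseline normalizes to ratio 1 everywhere
  fake <- bl$baseline
  fake[is.na(fake)] <- 0
  r <- normalize_cell(fake, bl$baseline)
  expect_true(all(abs(r[!is.na(r)] - 1) < 1e-12))

  # multiplying counts by k > 0 changes nothing downstream
  cell <- exp$meta$cell_id[exp$meta$gate == "S3"][1]
  r1 <- normalize_cell(wcm$counts[, cell], bl$baseline)
  r2 <- normalize_cell(wcm$counts[, cell] * 7L, bl$baseline)
  expect_equal(r1, r2)
  s1 <- binarize(r1)
  s2 <- binarize(r2)
  expect_identical(as.vector(s1), as.vector(s2))
  expect_equal(rep_score(s1), rep_score(s2))

  # all-zero cell is degenerate, not an error
  rz <- normalize_cell(rep(0L, length(bl$baseline)), bl$baseline)
  expect_true(isTRUE(attr(rz, "degenerate")))
  expect_true(all(is.na(rz)))
})

test_that("G2-like uniform coverage cancels to a flat ratio", {
  exp <- small_experiment()
  wcm <- wcm_from_bins(exp$genome, exp$counts)
  bl <- g1_baseline(wcm, exp$meta$cell_id[exp$meta$gate == "G1"])
  g2 <- exp$meta$cell_id[exp$meta$gate == "G2"][1]
  r <- normalize_cell(wcm$counts[, g2], bl$baseline)
  expect_lt(sd(r, na.rm = TRUE) / mean(r, na.rm = TRUE), 0.25)
  expect_equal(mean(r, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("binarize separates clusters and flags non-bimodal input", {
  ratio <- c(rep(1, 500), rep(2, 500))
  s <- binarize(ratio)
  expect_equal(which(s == 1), 501:1000)
  expect_false(attr(s, "non_bimodal"))

  flat <- binarize(rep(1.5, 100))
  expect_true(attr(flat, "non_bimodal"))
  expect_true(all(is.na(flat)))

  expect_error(binarize(rep(1, 5)), class = "screpli_degenerate_input")
})

test_that("rep_score is the mean of non-missing states", {
  expect_equal(rep_score(c(1L, 1L, 1L)), 1)
  expect_equal(rep_score(c(1L, 0L, 1L, 0L)), 0.5)
  expect_equal(rep_score(c(1L, NA, 0L, NA)), 0.5)
  expect_error(rep_score(c(NA_integer_, NA_integer_)),
               class = "screpli_undefined_result")
})

test_that("rep_score recovers s_fraction and respects CNV segments", {
  cfg <- sim_config(seed = 23, flip_noise = 0)
  cnv <- data.frame(chrom = "chr1", start_bin = 301, end_bin = 360, copy = 3)
  g <- make_genome(cfg, n_chrom = 1, bins_per_chrom = 900, n_genes = 0,
                   cnv = cnv)
  set.seed(41)
  g1_counts <- sapply(1:10, function(i)
    simulate_counts(g, simulate_cell(g, "G1"), depth = 100))
  colnames(g1_counts) <- paste0("G1_", 1:10)
  cell <- simulate_cell(g, "S3", s_fraction = 0.6, flip_noise = 0)
  sc <- simulate_counts(g, cell, depth = 100)
  counts <- cbind(g1_counts, S3_01 = sc)
  meta <- data.frame(cell_id = colnames(counts),
                     gate = c(rep("G1", 10), "S3"))
  prof <- scrt_profiles(wcm_from_bins(g, counts), meta)
  expect_equal(unname(prof$rep_scores["S3_01"]), 0.6, tolerance = 0.03)

  # CNV cancellation: state accuracy inside the copy-3 segment matches the
  # diploid remainder within 2%
  acc <- prof$state[, "S3_01"] == cell$states_true
  in_cnv <- seq_len(900) %in% 301:360
  expect_lt(abs(mean(acc[in_cnv], na.rm = TRUE) -
                  mean(acc[!in_cnv], na.rm = TRUE)), 0.02)
})

test_that("exported profiles round-trip and emit sorted half-open bedGraphs", {
  exp <- small_experiment()
  prof <- scrt_profiles(wcm_from_bins(exp$genome, exp$counts), exp$meta)
  out <- withr::local_tempdir()
  files <- export_profiles(prof, out)

  sm <- read_matrix_tsv(file.path(out, "state_matrix.tsv"))
  expect_equal(unname(sm), unname(prof$state))

  cid <- colnames(prof$state)[1]
  bg <- read_bedgraph(file.path(out, paste0(cid, "_state.bedGraph")))
  expect_equal(nrow(bg), sum(!is.na(prof$state[, cid])))
  expect_true(all(bg$start >= 0 & bg$end > bg$start))
  expect_true(!is.unsorted(bg$start))
})
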