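grid_windows <- function(size = 1e6, window = 2e5, step = 4e4) {
  make_windows(c(chr1 = size), window_spec(window, step))
}

test_that("assign_gene_rt uses the smallest-start containing window", {
  w <- grid_windows()
  rt <- seq_len(nrow(w)) / nrow(w)
  genes <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = 90000, end = 110000)  # midpoint 100,000
  out <- assign_gene_rt(rt, genes, w)
  # windows starting at 0, 40k, 80k all contain 100,000; smallest start wins
  expect_equal(out$rt_value, rt[which(w$start == 0)])

  # constant track -> every gene inherits the constant
  genes2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       start = c(1e4, 7e5), end = c(2e4, 7.4e5))
  out2 <- assign_gene_rt(rep(0.42, nrow(w)), genes2, w)
  expect_equal(out2$rt_value, c(0.42, 0.42))

  # genes outside the grid are excluded with a warning and counted
  genes3 <- data.frame(gene_id = "far", chrom = "chr9",
                       start = 0, end = 100)
  expect_warning(out3 <- assign_gene_rt(rt, genes3, w), "outside")
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_dropped"), 1)
})

test_that("assigned gene RT tracks the truth timing on a fixture", {
  exp <- small_experiment(seed = 17, census = c(G1 = 8, S2 = 6, S3 = 5, S4 = 6),
                          bins = 800, n_genes = 1200, flip_noise = 0.05)
  prof <- scrt_profiles(wcm_from_bins(exp$genome, exp$counts), exp$meta)
  pb <- pseudobulk_fraction(prof, cells = select_mid_s(exp$meta))
  gr <- assign_gene_rt(pb$rt, exp$genome$genes, pb$windows)
  truth <- gene_truth_rt(exp$genome)[gr$gene_id]
  expect_gt(cor(gr$rt_value, truth, method = "spearman"), 0.9)
})

test_that("filter_expressed_genes applies the strict log2 FPKM > 1 rule", {
  v <- rbind(boundary = c(2, 2, 2),    # log2 = 1 everywhere -> excluded
             one_hit = c(4.1, 0, 0),   # expressed once -> included
             silent = c(0, 0, 0))
  colnames(v) <- paste0("c", 1:3)
  m <- expression_matrix(v, "FPKM")
  expect_equal(filter_expressed_genes(m), "one_hit")
  empty <- expression_matrix(v["silent", , drop = FALSE], "FPKM")
  expect_length(filter_expressed_genes(empty), 0)
})

test_that("binned_probability groups genes deterministically by RT", {
  rt <- data.frame(gene_id = sprintf("g%03d", 1:100),
                   rt_value = (1:100) / 100)
  expressed <- setNames(c(rep(0, 50), rep(1, 50)), rt$gene_id)
  g <- binned_probability(rt, expressed, group_size = 50)
  expect_equal(g$p_expressed, c(0, 1))
  expect_equal(g$n_genes, c(50, 50))
  expect_true(!is.unsorted(g$mean_rt))

  # 120 genes -> 2 groups, 20 dropped
  rt120 <- data.frame(gene_id = sprintf("g%03d", 1:120),
                      rt_value = (1:120) / 120)
  e120 <- setNames(rep(c(0, 1), 60), rt120$gene_id)
  g120 <- binned_probability(rt120, e120, group_size = 50)
  expect_equal(nrow(g120), 2)
  expect_equal(attr(g120, "n_dropped"), 20)

  # input order never changes the groups
  set.seed(9)
  perm <- sample.int(100)
  g_perm <- binned_probability(rt[perm, ], expressed, group_size = 50)
  expect_equal(g_perm, g, ignore_attr = TRUE)

  expect_error(binned_probability(rt[1:60, ], expressed[1:60], 50),
               class = "screpli_insufficient_genes")
})

test_that("fit_slope matches closed-form OLS", {
  two_pt <- data.frame(mean_rt = c(0, 1), p_expressed = c(0, 1))
  f <- fit_slope(two_pt)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  flat <- data.frame(mean_rt = c(0.2, 0.4, 0.8),
                     p_expressed = c(0.5, 0.5, 0.5))
  expect_equal(fit_slope(flat)$slope, 0)

  # hand computation: sum xy / sum xx = 0.24 / 0.32
  toy <- data.frame(mean_rt = c(0.1, 0.5, 0.9),
                    p_expressed = c(0.2, 0.5, 0.8))
  expect_equal(fit_slope(toy)$slope, 0.75)

  degen <- data.frame(mean_rt = c(0.5, 0.5), p_expressed = c(0, 1))
  expect_equal(fit_slope(degen)$reason, "no RT variance")
})

test_that("per_cell_slope recovers constructed conditional probabilities", {
  n <- 2000
  w <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                  end = (1:n) * 1e5)
  states <- rep(c(0L, 1L), each = n / 2)
  genes <- data.frame(gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                      start = w$start + 100, end = w$start + 200)
  set.seed(13)
  p <- ifelse(states == 1, 0.9, 0.3)
  on <- rbinom(n, 1, p)
  expr <- setNames(ifelse(on == 1, 4, 0.5), genes$gene_id)  # log2: 2 vs -1
  fit <- per_cell_slope(states, expr, genes, w, genes$gene_id)
  expect_equal(fit$slope, 0.6, tolerance = 0.05)

  # a G1 cell (all states 0) has no RT variance
  g1 <- per_cell_slope(rep(0L, n), expr, genes, w, genes$gene_id)
  expect_true(is.na(g1$slope))
  expect_equal(g1$reason, "no RT variance")

  # expression independent of state -> slope near zero
  on_null <- rbinom(n, 1, 0.5)
  expr_null <- setNames(ifelse(on_null == 1, 4, 0.5), genes$gene_id)
  fit_null <- per_cell_slope(states, expr_null, genes, w, genes$gene_id)
  expect_lt(abs(fit_null$slope), 0.1)
})

test_that("signed-rank p values match exact enumeration", {
  # perfectly symmetric slopes -> p = 1
  expect_equal(slopes_signed_rank(c(1, -1, 2, -2, 3, -3)), 1)
  # all positive, n = 6: two-sided exact p = 2 / 2^6
  expect_equal(slopes_signed_rank(c(1, 2, 3, 4, 5, 6)), 2 / 64)
  expect_error(slopes_signed_rank(c(1, 2, 3, 4)),
               class = "screpli_insufficient_data")
  # zeros are dropped before testing
  expect_equal(slopes_signed_rank(c(0, 1, 2, 3, 4, 5, 6)), 2 / 64)
})

test_that("slope_vs_repscore handles exact and degenerate relationships", {
  tab <- data.frame(slope = c(1, 2, 3, 4), rep_score = c(0.1, 0.3, 0.5, 0.7))
  expect_equal(slope_vs_repscore(tab), 1)
  tab$slope <- -2 * tab$rep_score + 1
  expect_equal(slope_vs_repscore(tab), -1)
  flat <- data.frame(slope = c(1, 1, 1), rep_score = c(0.1, 0.2, 0.3))
  r <- slope_vs_repscore(flat)
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "zero variance")
  expect_error(slope_vs_repscore(tab[1:2, ]),
               class = "screpli_insufficient_data")
})

test_that("early/late split assigns the boundary to early and detects shifts", {
  genes <- sprintf("g%03d", 1:200)
  rt <- data.frame(gene_id = genes,
                   rt_value = c(0.5, seq(0, 1, length.out = 199)))
  v <- matrix(2^rnorm(400, 2), 200, 2, dimnames = list(genes, c("a", "b")))
  m <- expression_matrix(v, "FPKM")
  res <- early_late_expression_test(rt, m)
  expect_equal(res$n_early, sum(rt$rt_value >= 0.5))  # boundary gene early

  # genuinely higher expression in early genes is detected
  v2 <- v
  v2[rt$rt_value >= 0.5, ] <- v2[rt$rt_value >= 0.5, ] * 8
  res2 <- early_late_expression_test(rt, expression_matrix(v2, "FPKM"))
  expect_gt(res2$median_early, res2$median_late)
  expect_lt(res2$p, 0.01)

  # empty group is degenerate, not an error
  all_early <- transform(rt, rt_value = 0.9)
  res3 <- early_late_expression_test(all_early, m)
  expect_true(is.na(res3$p))
  expect_equal(res3$reason, "empty early or late group")
})
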