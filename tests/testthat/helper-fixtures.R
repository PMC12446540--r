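# Shared fixture builders and independent oracles. Fixtures are generated
# in code at test time; nothing is read from disk.

# Independent O(reads x windows) brute-force window counter, used as the
# oracle for count_windows.
brute_force_window_counts <- function(reads_df, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(reads_df$chrom == windows$chrom[i] &
          reads_df$pos >= windows$start[i] &
          reads_df$pos < windows$end[i])
  }, numeric(1))
}

# Small standard experiment used by several files; memoised per options.
local({
  cache <- new.env(parent = emptyenv())
  small_experiment <<- function(seed = 11, census = c(G1 = 6, S2 = 3, S3 = 3,
                                                      S4 = 3, G2 = 2),
                                bins = 400, n_genes = 600,
                                flip_noise = 0, depth = 100, b = 4) {
    key <- paste(seed, paste(names(census), census, collapse = ","),
                 bins, n_genes, flip_noise, depth, b, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(seed = seed, n_cells_per_gate = census,
                      depth = depth, flip_noise = flip_noise,
                      expr_slope = b)
    cache[[key]] <- simulate_experiment(cfg, n_chrom = 1,
                                        bins_per_chrom = bins,
                                        n_genes = n_genes)
    cache[[key]]
  }
})

# Study-census metadata table (13 G1, 6/6/5/6/6 S1-S5, 6 G2) without any
# simulation attached.
census_meta <- function() {
  census <- default_census()
  data.frame(
    cell_id = sprintf("%s_%02d", rep(names(census), census),
                      unlist(lapply(census, seq_len))),
    gate = rep(names(census), census),
    stringsAsFactors = FALSE
  )
}
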