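# screpli

Single-cell replication timing (RT) profiling and RT–expression
correlation for sorted-nuclei multiomics experiments.

## The problem

During S phase, the genome replicates in a reproducible temporal order:
some domains copy early, others late. A single S-phase nucleus carries this
order in its sequencing coverage — already-replicated windows sit at twice
the depth of not-yet-replicated ones. When the same nuclei also yield an
mRNA library, replication timing and gene expression can be correlated
*within individual cells*, not just across bulk populations.

`screpli` implements that analysis for plate-sorted designs in which nuclei
are gated on DNA content into G1, five S-phase gates S1–S5, and G2:

* **Single-cell RT profiles** — reads counted in 200 kb sliding windows at
  40 kb steps, normalized against the scaled mean of the G1 control cells
  (which cancels constitutive copy-number variation per window), binarized
  into replicated/unreplicated states by deterministic two-means on the
  log2 ratio, and summarized per cell by the **Rep score**, the fraction of
  the assessable genome already replicated.
* **Pseudo-bulk RT** — per window, the fraction of mid-S cells (gates
  S2–S4) already replicated, on a 0–1 scale with 1 = earliest; or,
  alternatively, all mid-S reads pooled into one entry and normalized like
  a single cell. Either profile can be compared to a reference bulk RT
  bedGraph by Spearman rank correlation with midpoint-containment matching.
* **RT–expression slope** — genes expressed nowhere (log2 FPKM ≤ 1 in all
  cells) are dropped; each gene inherits the RT of the window containing
  its midpoint; genes are sorted by RT and cut into groups of 50; per group
  the expression probability is regressed on mean RT by OLS. The slope has
  units of probability per RT unit. Within each cell the same procedure
  runs on the cell's binary states and its own expressed calls, so the
  per-cell slope estimates P(expressed | replicated) − P(expressed |
  unreplicated). Per-cell slopes are tested against the no-association
  median of 0 with a two-sided Wilcoxon signed-rank test and correlated
  (Pearson) with Rep score; genes are also split at RT ≥ 0.5 into early
  versus late and compared by rank-sum test.
* **A ground-truthed generator** — `simulate_experiment()` emulates the
  whole sorted design (default census: 13 G1, 6/6/5/6/6 S1–S5, 6 G2 = 48
  nuclei, 17 of them mid-S) with Poisson reads over a smoothed timing
  program and logistically RT-coupled expression, so every stage is
  testable by parameter recovery without any sequencing data.

## Worked example

```r
library(screpli)

res <- run_pipeline(run_config(seed = 42))
res$slopes
#> slope_table: 29 cells with defined slope (of 29 )
#>   median slope: 0.3651  signed-rank p: 2.702e-06  Pearson r(slope, Rep score): -0.035

res$report$pseudobulk_slope
#> [1] 0.6473038
```

Reading the numbers: all 29 S-phase cells yielded a defined RT–expression
slope; the median per-cell slope of 0.365 means a gene is, within a typical
mid-S cell, ~37 percentage points more likely to be expressed in its
replicated than in its unreplicated regions, and the signed-rank p of
2.7e-06 rejects the no-association null. The pseudo-bulk slope of 0.65
per RT unit is the population-level analogue (the generator's logistic
link rises from on-probability 0.12 to 0.88 across the RT range, and the
fitted line recovers that rise). The slope–Rep-score correlation is near
zero here because the generator gives every cell the same expression link;
on real data this is the quantity that asks whether RT–expression coupling
strengthens through S phase.

Lower-level entry points (`count_windows`, `g1_baseline`, `normalize_cell`,
`binarize`, `rep_score`, `pseudobulk_fraction`, `correlate_to_reference`,
`binned_probability`, `fit_slope`, `slope_table`, …) expose each stage
separately; `write_fixture()` / `read_fixture()` serialize a simulated
study as diff-able TSV/BED/JSON. A thin command-line wrapper with
`simulate`, `scrt`, `pseudobulk`, `rtcor` and `run` subcommands lives at
`inst/scripts/screpli.R`.

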