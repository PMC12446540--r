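---
title: "Methods: single-cell replication timing and its coupling to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell replication timing and its coupling to expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screpli)
```

## The measurement model

Replication timing (RT) describes when, during S phase, each genomic region
is copied. A cell partway through S phase carries two copies of its
not-yet-replicated regions and four chromatids' worth — effectively doubled
coverage — of its already-replicated regions. Sequencing the genomic DNA of
a single S-phase nucleus therefore encodes that cell's replication state in
its coverage profile: replicated windows sit at roughly twice the depth of
unreplicated ones.

`screpli` works with nuclei flow-sorted on DNA content into seven gates:
G1 (2N), five S-phase gates S1–S5 of increasing DNA content, and G2 (4N).
Phase labels always come from the sorting metadata; the package never
infers cell-cycle phase from the reads.

The analysis chain is:

1. **Window counting** (`count_windows`): reads are counted in sliding
   windows, by default 200 kb windows every 40 kb. Counting is implemented
   as 40 kb base-bin tabulation followed by rolling sums of five adjacent
   base bins, which is exact and linear in the number of bins; the test
   suite checks it against a brute-force overlap counter.
2. **G1 baseline** (`g1_baseline`): each G1 control cell is scaled to unit
   genome-wide mean; the per-window mean of the scaled controls is the
   baseline, and `2 * baseline / median(baseline)` estimates constitutive
   copy number per window. Windows below 5% of the median baseline are
   marked missing and stay missing everywhere downstream.
3. **Normalization** (`normalize_cell`): an S-phase cell is scaled to unit
   mean and divided per window by the baseline. Because the baseline is
   proportional to constitutive copy number, division cancels CNV per
   window: a copy-3 segment inflates numerator and denominator alike, so
   only replication-driven doubling survives in the ratio.
4. **Binarization** (`binarize`): per-window log2 ratios are split by
   deterministic one-dimensional two-means, with centers initialized at the
   25th/75th percentiles. The higher cluster is the replicated state. If
   the fitted centers are closer than 0.15 log2 units the profile is not
   bimodal — the signature of a G1/G2-like uniform genome — and the cell is
   flagged rather than binarized.
5. **Rep score** (`rep_score`): the fraction of non-missing windows in
   state 1; a Rep score of 0.6 means 60% of the assessable genome has
   replicated. It is the cell's position along S phase.

### Why these numerical choices

* *Mean (not median) library scaling* keeps Poisson expectations exact, so
  closed-form checks on the synthetic data hold without bias corrections.
* *Two-means with percentile initialization* was chosen because the ratio
  of a mid-S cell is, by construction, a two-component mixture around
  {c, 2c}; two-means is the assumption-lightest consistent classifier and,
  with deterministic initialization, reproducible bit for bit. The 0.15
  log2 separation floor is roughly 1.5× the coverage noise of a typical
  window at the default depth, so uniform profiles are reliably flagged
  while genuine mid-S bimodality (separation ≈ 1 log2 unit) never is.
* *Missing-data propagation*: a window missing in the baseline is missing
  in every cell; Rep scores and pseudo-bulk values are computed over
  non-missing windows only.

## Pseudo-bulk RT

Mid-S cells (gates S2–S4 by default) are the informative ones: with about
half the genome replicated, early and late domains separate maximally. Two
constructions are provided and cross-checked:

* **fraction** (default): per window, the fraction of informative cells
  already replicated — a direct, missing-data-aware timing estimate on a
  0–1 scale (1 = earliest). Windows informed by fewer than 3 cells are set
  missing.
* **pooled**: mid-S read counts are summed into a single synthetic entry,
  normalized exactly like one cell, then min–max rescaled to [0, 1] after
  winsorizing at the 1st/99th percentiles.

`correlate_to_reference` compares either profile to an external bulk RT
track by matching each window's midpoint to the containing reference
interval and computing Spearman's rho. Rank correlation makes the
comparison invariant to the reference's scale (often log2 early/late);
midpoint containment keeps the matching deterministic and resolution
agnostic. A strongly negative rho triggers a polarity warning instead of a
silent flip, because a silent flip would mask a genuine inversion of
early/late structure.

## The RT–expression statistic

The package quantifies the classical observation that early-replicating
regions are more often expressed, at two resolutions.

**Pseudo-bulk.** Genes expressed nowhere (log2 FPKM ≤ 1 in every cell) are
removed. Each remaining gene inherits the pseudo-bulk RT of the window
containing its midpoint (smallest-start window among the overlapping
sliding windows, a deterministic tie-break). Genes are sorted by RT —
ties broken by gene id so group composition is reproducible — and cut into
consecutive groups of exactly 50 genes, dropping the trailing partial group
so every probability has the same denominator. Per group we record the mean
RT and the expression probability, and fit an ordinary least-squares line;
the slope (probability per RT unit) is the statistic. For the per-gene
expression value at pseudo-bulk level the package uses the fraction of
mid-S cells in which the gene is expressed: the standard binary call
(expressed iff log2 FPKM > 1, boundary excluded) averaged over cells. This
choice keeps the group probability an unbiased estimate of the underlying
per-cell on-probability, which is what makes the generator's recovery test
analytic (below).

**Per cell.** The only per-cell RT the data afford is the binary
replication state, so the same sort–bin–fit procedure runs with each cell's
0/1 states as gene RT and that cell's own expressed calls. The slope then
estimates P(expressed | replicated) − P(expressed | unreplicated) for that
cell. Cells with no RT variance among retained genes (fully unreplicated or
fully replicated genomes) are reported as undefined with a reason rather
than dropped silently.

**Population tests.** The per-cell slopes are tested against the
no-association condition (median slope = 0) with a two-sided Wilcoxon
signed-rank test — exact for ≤ 25 non-zero slopes, normal approximation
with continuity correction beyond — and related to S-phase progression via
the Pearson correlation of slope against Rep score. Genes are also split at
pseudo-bulk RT ≥ 0.5 (early; the boundary is assigned to early) versus
< 0.5 (late) and compared on per-gene mean log2 FPKM with a rank-sum test.
No multiple-testing correction is applied to the marker-gene phase
comparisons; they are reported with their raw Welch t-test p values and a
0.05 cutoff.

## The synthetic experiment

The generator emulates the sorted-nuclei study design so every stage has a
parameter-recovery surface:

* **Genome** (`make_genome`): per chromosome, standard normal noise is
  smoothed by a moving average of `rt_smoothness` bins (default 10, i.e.
  2 Mb domains at 200 kb bins) and rank-rescaled genome-wide to [0, 1] —
  contiguous early and late domains with a known, exactly uniform timing
  distribution. Optional CNV segments set constitutive copy to 1 or 3 over
  contiguous runs.
* **Cells** (`simulate_cell`): a cell at S-phase fraction *s* replicates
  exactly the earliest *s* of the genome (threshold on timing), then each
  window flips independently with probability `flip_noise` (default 0.05).
  This threshold-plus-flips model is the simplest one consistent with a
  mid-S cell having ~50% of its genome replicated; no stochastic-firing
  kinetics are modeled. Gate-to-fraction mapping: G1 = 0, S1–S5 at the five
  equal-quantile centers 0.1/0.3/0.5/0.7/0.9, G2 = 1.
* **Census**: 13 G1, 6/6/5/6/6 in S1–S5, 6 G2 — 48 nuclei, 29 S-phase,
  17 mid-S.
* **Reads** (`simulate_counts`): Poisson with mean
  `depth * copy/2 * (1 + state)` (default depth 100 per 200 kb window,
  i.e. ~2 reads/kb in unreplicated diploid regions). Poisson keeps every
  moment check closed-form; an overdispersion knob switches to negative
  binomial when heavier tails are wanted.
* **Expression** (`simulate_expression`): gene *g* with RT *r* is "on" in
  each cell independently with probability `plogis(a + b r)` (defaults
  a = −2, b = 4: on-probability rising from 0.12 in the latest to 0.88 in
  the earliest regions). On genes emit log2 FPKM ~ N(4, 1.5) truncated to
  > 1; off genes N(−2, 1) truncated to ≤ 1. The truncation makes the
  binary expressed call coincide exactly with the latent on state, so the
  expected fitted slope is the OLS slope of the logistic curve over the
  realized gene RT distribution — an analytic target the acceptance suite
  verifies with an explicit binomial Monte-Carlo band.

What the generator does **not** emulate: mappability/GC bias, amplification
artifacts, read-level sequence content, bursty transcription, doublets, or
empty wells. Passing recovery tests therefore demonstrates correctness of
the algorithms under the stated read model, not robustness to every
artifact of real libraries.

## Problem sizes and calibration checks

The shipped tests run the chain at deliberately modest sizes — genomes of
400–2000 windows, 1500–5000 genes, the 48-cell census — chosen so that the
binomial/Poisson error bands are tight enough to detect real defects
(e.g. Rep-score recovery to ±0.03, binarization accuracy ≥ 0.97) while the
whole suite stays interactive. The null calibration of the signed-rank
machinery re-simulates expression 500 times over a fixed set of 17 mid-S
state vectors (under the null the slopes depend only on expression
randomness, so fixing states loses nothing) and checks the rejection rate
at alpha = 0.05 lands in 5% ± 2%.

```{r pipeline}
res <- run_pipeline(run_config(seed = 1, n_chrom = 1,
                               bins_per_chrom = 300, n_genes = 1500))
res$report$n_mid_s
res$report$pseudobulk_slope
res$report$signed_rank_p
```

## Known limitations

* The pooled pseudo-bulk route applies normalization and rescaling only; no
  smoothing or segmentation is layered on top, so it is noisier than the
  fraction route at small cell numbers.
* Per-cell RT is binary; sub-window replication progress within a cell is
  not modeled, and the per-cell slope is correspondingly a difference of
  two conditional probabilities, not a dose-response curve.
* In this generator all cells share one expression link, so the slope–Rep
  score correlation has no built-in trend; the package reports whatever
  the data give. Real cells may couple the two, which is exactly what the
  statistic is for.
* BAM/FASTQ ingestion is out of scope; inputs are positions, pre-binned
  counts, or the plain-text fixture formats.
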