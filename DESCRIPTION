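Package: screpli
Title: Single-Cell Replication Timing Profiles and RT-Expression Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives single-cell replication timing (RT) profiles from
    S-phase read counts normalized against G1-phase control cells, with
    per-window copy-number adjustment, two-means binarization and Rep
    scores; builds pseudo-bulk RT profiles from mid-S-phase cells and
    compares them to reference bulk RT tracks; and quantifies the
    association between RT and gene expression with a binned
    expression-probability slope statistic at pseudo-bulk and per-cell
    resolution, including Wilcoxon signed-rank and rank-sum population
    tests. Ships a ground-truthed synthetic-data generator emulating a
    sorted-nuclei (G1, S1-S5, G2) single-cell multiomics experiment so
    every stage can be tested by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
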