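# k9diff

Differential analysis of H3K9me3 heterochromatin domains from binned
ChIP-seq signal, with repeat-element enrichment statistics.

## The problem

H3K9me3 silences repetitive DNA — LTR retroelements (ERV1, ERVL,
ERVL-MalR), SINEs (Alu, MIR), satellites — and some genes. Comparing two
cell states (drug-sensitive vs resistant, knockdown vs control) asks three
questions: *where* are the broad H3K9me3 domains, *which* of them gain or
lose the mark between states, and *are the changing domains concentrated on
particular repeat families*? `k9diff` answers all three from 200-bp binned
coverage tracks (bedGraph), for analysts who have aligned and binned their
ChIP-seq data and want a deterministic, testable pipeline downstream of
that point.

## The method

Starting from per-sample IP and input tracks over a chromosome-sizes
genome model:

1. **Quantile normalization** across samples (IP and input separately):
   the value of genome-wide rank *r* in each sample is replaced by the mean
   of the rank-*r* values across samples.
2. **Noise reduction**: bin-wise IP − input.
3. **Broad peak calling** with two cutoffs: strong cores (signal ≥ peak
   cutoff, e.g. 1000 or 850) extended by weak segments (≥ linking cutoff,
   e.g. 500 or 425), with weak segments linked across gaps ≤ 800 bp.
4. **Union peak set**: concatenate → sort → merge → consecutive cluster ids.
5. **Signal matrices**: mean noise-reduced signal in 50 bins over a 10-kb
   window around each region centre, per condition.
6. **K-means** (Lloyd + k-means++, seeded) on the concatenated
   per-condition rows; clusters labelled **gain** / **loss** / **common**
   by the pseudocounted fold change of cluster mean signal,
   (m_B + 1)/(m_A + 1) against a 1.5-fold threshold.
7. **Obs/Exp enrichment**: differential regions are shuffled across the
   genome *n* = 3 times preserving lengths; for each repeat class or
   subfamily the ratio r_i = observed / expected_i is formed per shuffle
   and a one-sample t-test (df = n − 1) asks whether the mean ratio
   exceeds 1. An optional calibrated empirical permutation p-value from a
   larger shuffle count is also reported (recommended for specificity
   claims; see the methods vignette).

A synthetic-data generator (`sim_config()`, `simulate_dataset()`) plants
common/gain/loss domains and repeat-class enrichment with a truth table, so
the whole pipeline is testable offline.

## Worked example

```r
library(k9diff)

ds  <- simulate_dataset(sim_config(seed = 42))   # 2 x 2 Mb, planted domains
res <- run_pipeline(ds$tracks, repeats = ds$repeats,
                    peak_cutoff = 30, link_cutoff = 15,
                    seed = 42, n_empirical = 99)

length(res$union)          # union regions across both conditions
#> [1] 96
table(res$labels)          # gain / loss / common classification
#> common   gain   loss
#>     54     20     22
res$enrichment_class[, c("group", "observed", "mean_ratio", "t_stat",
                         "p_value", "p_empirical")]
#>     group observed mean_ratio t_stat p_value p_empirical
#> 1     LTR       34      3.783   5.11  0.0181        0.01
#> 2    SINE        9      0.616 -14.33  0.9976        0.93
#> 3 NEUTRAL       5       0.685 -10.60  0.9956        0.90
```

The generator planted 30 common, 20 gain and 20 loss domains, anchoring
differential domains on LTR elements with probability 0.8. The pipeline
recovers the differential counts (20 gain, 22 loss), and the Obs/Exp
statistic flags LTR as strongly enriched (observed 34 overlapping regions
vs ≈ 9 expected by chance; mean ratio 3.8, one-sided t-test p = 0.018,
empirical p = 0.01) while SINE and the neutral class show ratios below 1
and non-significant p-values. `region_size_stats()`,
`percent_associated()` and `repeat_composition()` give the region-size,
association-percentage and catalogue-composition summaries; with a gene
annotation, `extract_promoters()` feeds promoter association.

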