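---
title: "Identifying differential H3K9me3 heterochromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying differential H3K9me3 heterochromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(k9diff)
```

## The analysis problem

H3K9me3 marks constitutive heterochromatin, where it silences repetitive
elements (LTR retroelements such as the endogenous retrovirus families ERV1,
ERVL and ERVL-MalR; SINEs such as Alu and MIR; satellites) and a smaller set
of genes. When two cell states are compared — for example drug-sensitive
versus drug-resistant lines, or a knockdown versus its control — domains of
this mark can be gained, lost, or left unchanged, and the differential
domains tend to concentrate on particular repeat families.

`k9diff` implements that comparison as a reusable pipeline over 200-bp
binned ChIP-seq coverage:

1. **Quantile normalization** across samples (IP and input normalized as
   separate groups), forcing a common genome-wide signal distribution.
2. **Noise reduction**: bin-wise subtraction of the matched input track from
   each IP track.
3. **Broad peak calling** with a two-cutoff scheme: strong cores above a
   peak cutoff, extended by weaker flanks above a linking cutoff, with
   nearby weak segments linked across small gaps.
4. **Union peak set**: per-sample peaks concatenated, sorted, merged and
   given consecutive cluster ids.
5. **Signal matrices**: for every union region, the mean noise-reduced
   signal in 50 bins spanning a 10-kb window around the region centre, one
   matrix per condition.
6. **K-means classification** of regions into clusters, labelled *gain*,
   *loss* or *common* from the ratio of cluster mean signal between the two
   conditions.
7. **Repeat/promoter association and enrichment**: each region is annotated
   against a RepeatMasker-style catalogue and, optionally, promoters
   (±1 kb around the TSS, duplicates removed); differential regions are
   compared with length-preserving random redistributions of themselves to
   form observed/expected ratios per repeat class or subfamily.

## The observed/expected statistic

For a set of differential regions and a repeat group $g$, the *observed*
count $O_g$ is the number of regions overlapping (≥ 1 bp) at least one
element of $g$. The regions are then redistributed uniformly across the
genome $n$ times (default $n = 3$), preserving each region's length, with
the chromosome drawn proportionally to its number of valid start positions.
Each shuffle $i$ yields an expected count $E_{g,i}$ and a ratio
$r_i = O_g / E_{g,i}$ — one ratio per shuffle, not a ratio against the mean
expected count. A one-sample t-test with $n - 1$ degrees of freedom tests
whether the mean ratio exceeds 1 (one-sided).

Two caveats are reported honestly rather than hidden:

* **The t-test is anti-conservative under the null.** All $n$ ratios share
  the single observed numerator $O_g$, so the within-sample spread reflects
  only shuffle noise, not the sampling variability of $O_g$; in addition
  $\mathbb{E}[O/E] > 1$ for small counts (Jensen's inequality applied to
  $1/E$). In simulations at desk scale the nominal 5% level rejects about
  10–12% of the time. This is the price of the three-shuffle design; the
  test is kept because it is the field's reporting convention for this
  statistic.
* **A calibrated alternative is provided.** With `n_empirical > 0`,
  `obs_exp_enrichment()` draws that many additional shuffles and reports the
  permutation p-value $p = (1 + \#\{E_j \ge O\}) / (n_{\mathrm{emp}} + 1)$,
  which is slightly conservative (counts are discrete) but calibrated:
  measured null rejection at $\alpha = 0.05$ is 3.5–4.5% with 99 null
  shuffles. Specificity claims (e.g. "the neutral class is not enriched")
  should use this p-value.

Groups with any $E_{g,i} = 0$ are flagged `expected-zero` and excluded from
testing; zero-spread ratios are flagged `sd-zero`. Groups are restricted to
those overlapping the real set or at least one shuffled set.

## Clustering design

Features for k-means are the per-condition matrix rows concatenated
(2 × 50 values per region with the defaults), Lloyd's algorithm with
k-means++ initialization, `n_init` restarts, and the best within-cluster sum
of squares kept; everything is deterministic given a seed.

Two choices were genuinely open and were settled by simulation:

* **Row normalization.** On raw signal, Euclidean distance is dominated by
  how many bins a domain covers, so clusters form along domain *length*
  rather than condition *pattern*: a short domain present in both
  conditions sits closer to a short one-condition domain than to a long
  domain present in both. Dividing each feature row by its Euclidean norm
  makes the clustering respond to the shape and condition-asymmetry of the
  signal. The pipeline driver therefore uses `row_normalize = "l2"`;
  `kmeans_cluster()` itself defaults to raw features so the bare operation
  remains the textbook one, and `"sd"` (centre/scale) is also available.
* **Number of clusters.** The driver default is `k = 4`: one cluster per
  expected class (gain/loss/common) plus one spare, so that a class that is
  internally heterogeneous (common domains vary most in length) can occupy
  two clusters without stealing a cluster from another class. The
  per-cluster gain/loss/common labelling re-merges clusters of equal label,
  so `k` need not match the number of biological classes exactly. The
  driver also uses `n_init = 100` restarts: the objective has
  near-degenerate local optima at this problem size and restarts are cheap.

Cluster labels come from the pseudocounted fold change between cluster mean
signals, $(m_B + 1) / (m_A + 1) \ge 1.5$ for *gain* (and symmetrically for
*loss*); the pseudocount keeps ratios stable when means approach zero, and
the threshold is exposed as `fold_threshold`.

## The broad-peak caller

Peaks are called on noise-reduced tracks: maximal runs of bins at or above
`peak_cutoff` form strong cores (discarded if shorter than
`min_peak_length`, default one bin); maximal runs at or above `link_cutoff`
form weak segments; weak segments separated by at most `max_link_gap` bp
(default 800) are linked; every linked weak segment containing a surviving
strong core is reported with the weak-segment bounds. The historical cutoff
pairs for this analysis type are 1000/500 and 850/425 signal units on
quantile-normalized, input-subtracted tracks; the geometry parameters
(`min_peak_length`, `max_link_gap`) are not dictated by the cutoffs and are
exposed with conventional broad-calling defaults.

## What the synthetic generator emulates

`sim_config()` defines the study conditions used by the test suite and the
acceptance script, all overridable but chosen once:

* a 2 × 2 Mb genome at 200-bp bins — large enough for ~1300 repeat elements
  and 70 domains at realistic densities, small enough that the full
  pipeline runs in seconds;
* a repeat catalogue with classes LTR (ERV1, ERVL, ERVL-MalR; 100/100/150
  elements of 300–800 bp), SINE (Alu 400 × 250–350 bp, MIR 250 ×
  100–250 bp) and a NEUTRAL class (300 × 200–500 bp), giving each class a
  footprint of a few percent of the genome, in the spirit of genome-wide
  repeat densities; a Satellite entry (2–8 kb) exists in the default table
  with count 0;
* 30 common, 20 gain and 20 loss domains of 600–3000 bp; differential
  domains are centred on a random LTR element with probability
  `p_enrich = 0.8`, otherwise placed uniformly — this plants the ≥ 1 bp
  overlap that the enrichment statistic counts;
* Poisson bin counts: input mean 20, IP background mean 20, +60 inside
  active domains (common domains active in both conditions, gain only in
  the second, loss only in the first). The domain amplitude sits far above
  the corresponding peak cutoff (half the amplitude), so the acceptance
  checks do not operate at the caller's decision boundary; boundary
  behaviour is tested separately with explicit small tracks.

The generator emulates binned coverage directly rather than reads: the
pipeline's first real input is a binned track, so read-level simulation
would add nothing testable. It does not emulate mappability bias, duplicate
reads, copy-number changes, spike-in chromatin, or the heavy-tailed
clustering of real repeat families — so passing tests demonstrate the
pipeline's statistical behaviour under its own model assumptions, not
performance on real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open at every file boundary (BED/bedGraph
  native) and 1-based closed inside R (`GRanges` convention).
* Quantile normalization resolves ties by giving all members of a tied run
  the mean of the reference distribution over the tied rank span, which
  preserves each sample's total signal; with ties present, the normalized
  samples' sorted vectors need no longer coincide exactly (they do on
  tie-free data, where the procedure is also idempotent).
* Negative noise-reduced values are kept, not clamped: the peak cutoffs
  make them irrelevant for calling, and clamping would silently change the
  matrices fed to clustering.
* Signal-matrix windows extending past a chromosome end count the missing
  bins as zeros, in both numerator and denominator of the bin mean.
* `shuffle_intervals()` permits overlaps among placed intervals and applies
  no exclusion mask; the TSS of a minus-strand gene is its end coordinate;
  promoter duplicate removal means exact coordinate identity, not overlap.
* K-means ties (equidistant centres) break toward the lowest-index centre;
  an emptied cluster is reseeded at the point farthest from its centre;
  `sample.int`-based k-means++ makes every run reproducible from the seed.
* The problem sizes exercised by the tests — 2 × 2 Mb genomes, ≤ 10 kb
  oracle genomes, 20 seeds for the recovery study, 1000 replicates for the
  calibration study — were chosen so the whole suite completes in minutes
  while keeping Monte-Carlo error well below the asserted margins.

## Known limitations

* Exactly two conditions are supported by the driver (the classification
  contrast is a pair); the component operations are n-condition clean.
* With three shuffles the t-test's null behaviour is approximate at best
  (see above); use `n_empirical` for calibrated inference.
* Cluster-level labelling cannot rescue an individual region that k-means
  places in a cluster of another label; at the synthetic generator's
  default noise level this affects roughly 0–2 short, weak common domains
  per dataset.
* The bedGraph reader requires bin-grid-aligned intervals by design — the
  pipeline is defined on fixed bins, and silent re-binning would hide
  upstream errors.
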