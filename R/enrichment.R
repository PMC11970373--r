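#' Annotate regions with their overlap against an annotation set
#'
#' For each query region, `overlap_bp` is the number of its base pairs covered
#' by the union of the annotation intervals, `overlap_fraction` is that count
#' divided by the region length, and a region is `associated` when at least
#' one base pair overlaps.
#'
#' @param regions Query `GRanges`.
#' @param annotation Annotation `GRanges` (strand ignored).
#' @return data.frame with columns `overlap_bp`, `overlap_fraction`,
#'   `associated`, one row per query region in input order.
#' @export
overlap_annotate <- function(regions, annotation) {
  red <- GenomicRanges::reduce(GenomicRanges::granges(annotation),
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(regions, red, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    regions[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  bp <- numeric(length(regions))
  if (length(hits)) {
    agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    bp[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(overlap_bp = bp,
             overlap_fraction = bp / GenomicRanges::width(regions),
             associated = bp >= 1)
}

#' Percentage of regions associated with an annotation
#'
#' @param regions Non-empty query `GRanges`.
#' @param annotation Annotation `GRanges`.
#' @return Percentage (0-100) of query regions with >= 1 bp overlap.
#' @export
percent_associated <- function(regions, annotation) {
  if (length(regions) == 0L) stop("percent_associated: empty region set")
  100 * mean(overlap_annotate(regions, annotation)$associated)
}

#' Length-preserving random redistribution of intervals across the genome
#'
#' Each interval is independently replaced by an interval of identical length:
#' the chromosome is drawn with probability proportional to its number of
#' valid start positions (`L - len + 1`) and the start is uniform over them.
#' Overlaps among shuffled intervals are permitted; no exclusion mask is
#' applied. Consumes the current RNG stream (seed the caller for
#' reproducibility).
#'
#' @param regions `GRanges` to shuffle.
#' @param genome A [genome_model()].
#' @return `GRanges` of shuffled intervals; the multiset of lengths equals the
#'   input's.
#' @export
shuffle_intervals <- function(regions, genome) {
  n <- length(regions)
  si <- genome_seqinfo(genome)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqinfo(gr) <- si
    return(gr)
  }
  len <- GenomicRanges::width(regions)
  # valid start positions per (chromosome x region)
  vn <- outer(genome$length, len, function(L, l) pmax(L - l + 1, 0))
  tot <- colSums(vn)
  if (any(tot == 0)) {
    stop("shuffle_intervals: region longer than every chromosome")
  }
  cp <- apply(vn, 2L, cumsum)                       # nchrom x n
  if (is.null(dim(cp))) cp <- matrix(cp, nrow = 1L)
  u <- stats::runif(n) * tot
  ci <- colSums(cp < matrix(u, nrow = nrow(cp), ncol = n, byrow = TRUE)) + 1L
  starts0 <- floor(stats::runif(n) * vn[cbind(ci, seq_len(n))])
  gr <- GenomicRanges::GRanges(
    seqnames = genome$chrom[ci],
    ranges = IRanges::IRanges(start = starts0 + 1, width = len))
  GenomeInfoDb::seqlevels(gr) <- genome$chrom
  GenomeInfoDb::seqinfo(gr) <- si
  gr
}

# Count, per (set, group), the number of query regions hitting >= 1 element
# of the group ("regions"), or the number of (region, element) overlap pairs
# ("events"). `q` holds all query sets concatenated, `set_id` one integer
# per element of `q`. One findOverlaps call serves every set. Returns a
# n_sets x length(levels) matrix (set ids assumed 1..n_sets).
count_group_hits <- function(q, set_id, n_sets, repeats, group, levels,
                             count = c("regions", "events")) {
  count <- match.arg(count)
  hits <- GenomicRanges::findOverlaps(q, repeats, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  g <- group[S4Vectors::subjectHits(hits)]
  if (count == "regions") {
    keep <- !duplicated(paste(qi, g, sep = "\r"))
    g <- g[keep]
    qi <- qi[keep]
  }
  tab <- table(factor(set_id[qi], levels = seq_len(n_sets)),
               factor(g, levels = levels))
  matrix(as.numeric(tab), nrow = n_sets, dimnames = list(NULL, levels))
}

#' Observed/expected repeat (or annotation-group) enrichment with shuffle null
#'
#' The query regions are randomly redistributed across the genome
#' `n_shuffles` times ([shuffle_intervals()]). Groups (repeat classes or
#' subfamilies) are restricted to those overlapping the real set or at least
#' one shuffled set. Per group: observed = number of query regions associated
#' with the group's elements; expected_i = the same count for shuffled set i;
#' ratio_i = observed / expected_i (one ratio per shuffle, not
#' observed / mean(expected)). A one-sample t-test with `df = n_shuffles - 1`
#' tests whether the mean ratio exceeds `mu0 = 1` (one-sided). Groups with any
#' expected_i = 0 are flagged `"expected-zero"` and not tested; groups whose
#' ratios have zero spread are flagged `"sd-zero"`.
#'
#' Because the `n_shuffles` ratios share one observed numerator, the t-test is
#' anti-conservative under the null. When `n_empirical > 0`, an additional
#' calibrated permutation p-value is reported:
#' `p = (1 + #(expected_j >= observed)) / (n_empirical + 1)` over
#' `n_empirical` further shuffles.
#'
#' @param regions Non-empty query `GRanges` (e.g. differential peaks).
#' @param repeats `GRanges` with `repeat_class` / `repeat_subfamily` metadata
#'   columns ([read_repeat_bed()]), or any annotation with those columns.
#' @param genome A [genome_model()]; the universe over which regions are
#'   redistributed.
#' @param grouping `"class"` or `"subfamily"`.
#' @param n_shuffles Number of shuffled sets for the ratio statistic
#'   (default 3; must be >= 2).
#' @param seed Integer seed (or `NULL` to consume the current RNG stream).
#' @param mu0 Null mean ratio (default 1).
#' @param n_empirical Number of extra shuffles for the empirical p-value
#'   (default 0 = off).
#' @param count `"regions"` (each query region counted at most once per group)
#'   or `"events"` (every region-element overlap pair counted).
#' @return data.frame, one row per retained group: `group`, `n_elements`,
#'   `observed`, `expected_1..n`, `ratio_1..n`, `mean_ratio`, `sd_ratio`,
#'   `t_stat`, `df`, `p_value`, `flag`, and `p_empirical` when requested.
#' @export
obs_exp_enrichment <- function(regions, repeats, genome,
                               grouping = c("class", "subfamily"),
                               n_shuffles = 3, seed = NULL, mu0 = 1,
                               n_empirical = 0,
                               count = c("regions", "events")) {
  grouping <- match.arg(grouping)
  count <- match.arg(count)
  if (length(regions) == 0L) stop("obs_exp_enrichment: empty region set")
  if (n_shuffles < 2) {
    stop("obs_exp_enrichment: n_shuffles must be >= 2 (t-test needs df >= 1)")
  }
  mc <- S4Vectors::mcols(repeats)
  gcol <- if (grouping == "class") "repeat_class" else "repeat_subfamily"
  if (!gcol %in% names(mc)) {
    stop("obs_exp_enrichment: annotation lacks the '", gcol, "' column")
  }
  group <- as.character(mc[[gcol]])
  levels_all <- unique(group)
  stopifnot(inherits(genome, "genome_model"))

  # all shuffle sets are drawn in two batched calls (ratio shuffles first,
  # so the main statistic does not depend on n_empirical) and counted
  # through one findOverlaps pass over the concatenated sets
  n <- length(regions)
  with_seed(seed, {
    shuf <- shuffle_intervals(rep(regions, n_shuffles), genome)
    emp <- if (n_empirical > 0) {
      shuffle_intervals(rep(regions, n_empirical), genome)
    } else NULL
  })
  q <- GenomicRanges::granges(regions)
  GenomeInfoDb::seqinfo(q) <- genome_seqinfo(genome)
  q <- c(q, shuf)
  if (!is.null(emp)) q <- c(q, emp)
  n_sets <- 1L + n_shuffles + n_empirical
  set_id <- rep.int(seq_len(n_sets), rep.int(n, n_sets))

  counts <- count_group_hits(q, set_id, n_sets, repeats, group,
                             levels_all, count)
  observed <- counts[1L, ]
  expected <- t(counts[1L + seq_len(n_shuffles), , drop = FALSE])

  # "overlaps in at least one of the files": real set or any shuffled set
  keep <- observed > 0 | rowSums(expected > 0) > 0
  levels_keep <- levels_all[keep]
  observed <- observed[keep]
  expected <- expected[keep, , drop = FALSE]

  n_el <- as.numeric(table(factor(group, levels = levels_keep)))
  ratios <- observed / expected
  flag <- rep("", length(levels_keep))
  flag[apply(expected == 0, 1L, any)] <- "expected-zero"
  m <- rowMeans(ratios)
  s <- apply(ratios, 1L, stats::sd)
  flag[flag == "" & s == 0] <- "sd-zero"
  ok <- flag == ""
  t_stat <- ifelse(ok, (m - mu0) / (s / sqrt(n_shuffles)), NA_real_)
  p <- ifelse(ok, stats::pt(t_stat, df = n_shuffles - 1, lower.tail = FALSE),
              NA_real_)
  out <- data.frame(group = levels_keep, n_elements = n_el,
                    observed = observed, stringsAsFactors = FALSE)
  for (i in seq_len(n_shuffles)) out[[paste0("expected_", i)]] <- expected[, i]
  for (i in seq_len(n_shuffles)) out[[paste0("ratio_", i)]] <- ratios[, i]
  out$mean_ratio <- ifelse(flag == "expected-zero", NA_real_, m)
  out$sd_ratio <- ifelse(flag == "expected-zero", NA_real_, s)
  out$t_stat <- t_stat
  out$df <- n_shuffles - 1
  out$p_value <- p
  out$flag <- flag
  if (n_empirical > 0) {
    emp_counts <- t(counts[1L + n_shuffles + seq_len(n_empirical), ,
                           drop = FALSE])[keep, , drop = FALSE]
    out$p_empirical <- (1 + rowSums(emp_counts >= observed)) /
      (n_empirical + 1)
  }
  rownames(out) <- NULL
  out
}

#' Subfamily composition of a repeat class
#'
#' @param repeats `GRanges` with `repeat_class` / `repeat_subfamily` columns.
#' @param class_name Repeat class to tabulate (e.g. `"LTR"`).
#' @return data.frame with `subfamily`, `n`, `percent` (of elements in the
#'   class), sorted by decreasing count.
#' @export
repeat_composition <- function(repeats, class_name) {
  mc <- S4Vectors::mcols(repeats)
  sel <- mc$repeat_class == class_name
  if (!any(sel)) stop("repeat_composition: unknown class '", class_name, "'")
  tab <- sort(table(as.character(mc$repeat_subfamily[sel])), decreasing = TRUE)
  data.frame(subfamily = names(tab), n = as.numeric(tab),
             percent = 100 * as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Drop repeat elements carrying no signal
#'
#' Keeps an element iff the sum of track values over the bins overlapping it
#' is strictly positive. Order is preserved.
#'
#' @param elements `GRanges` of repeat elements.
#' @param track A [binned_track()] (e.g. noise-reduced H3K9me3 signal).
#' @return The positive-signal subset of `elements`.
#' @export
filter_repeats_with_signal <- function(elements, track) {
  if (length(elements) == 0L) return(elements)
  elements2 <- validate_regions(elements, track$genome)
  w <- track$bin_width
  chrom <- as.character(GenomeInfoDb::seqnames(elements2))
  start0 <- GenomicRanges::start(elements2) - 1
  end0 <- GenomicRanges::end(elements2)
  cs <- lapply(track$values, function(v) c(0, cumsum(v)))
  k0 <- start0 %/% w                 # first overlapped bin (0-based)
  k1 <- ceiling(end0 / w) - 1        # last overlapped bin
  sums <- vapply(seq_along(elements2), function(i) {
    cc <- cs[[chrom[i]]]
    cc[min(k1[i] + 2, length(cc))] - cc[k0[i] + 1]
  }, numeric(1))
  elements[sums > 0]
}
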