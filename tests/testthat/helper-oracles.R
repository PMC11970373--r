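# Independent brute-force oracles and tiny-fixture builders.
# These re-derive expected results by direct enumeration (per-base or
# per-bin), deliberately sharing no code with the implementation.

gr0 <- function(chrom, start0, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end),
                         strand = rep(strand, length.out = length(chrom)))
}

bed0 <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

# naive two-cutoff broad caller on one chromosome's bin vector; returns
# 0-based half-open bp intervals. Scans bins with explicit loops.
bf_broad_peaks_chrom <- function(v, w, L, peak_cutoff, link_cutoff,
                                 min_peak_length, max_link_gap) {
  nb <- length(v)
  seg_of <- function(flag) {
    segs <- list()
    i <- 1
    while (i <= nb) {
      if (flag[i]) {
        j <- i
        while (j < nb && flag[j + 1]) j <- j + 1
        segs[[length(segs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    segs
  }
  bp <- function(seg) c((seg[1] - 1) * w, min(seg[2] * w, L))
  strong <- Filter(function(s) {
    b <- bp(s); (b[2] - b[1]) >= min_peak_length
  }, seg_of(v >= peak_cutoff))
  weak <- seg_of(v >= link_cutoff)
  if (!length(weak) || !length(strong)) return(NULL)
  # link weak segments greedily left to right
  linked <- list(bp(weak[[1]]))
  for (s in weak[-1]) {
    b <- bp(s)
    last <- linked[[length(linked)]]
    if (b[1] - last[2] <= max_link_gap) {
      linked[[length(linked)]] <- c(last[1], b[2])
    } else linked[[length(linked) + 1]] <- b
  }
  keep <- Filter(function(lk) {
    any(vapply(strong, function(s) {
      b <- bp(s); b[1] >= lk[1] && b[2] <= lk[2]
    }, logical(1)))
  }, linked)
  if (!length(keep)) return(NULL)
  do.call(rbind, keep)
}

# per-base union-of-intervals merge with gap closing; one chromosome,
# 0-based half-open input/output
bf_merge_chrom <- function(starts0, ends, L, merge_distance) {
  covered <- logical(L)
  for (i in seq_along(starts0)) covered[(starts0[i] + 1):ends[i]] <- TRUE
  if (merge_distance > 0) {
    # close gaps of length <= merge_distance between covered runs
    r <- rle(covered)
    pos <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1 && k < length(r$values) &&
          r$lengths[k] <= merge_distance) {
        covered[(pos[k] - r$lengths[k] + 1):pos[k]] <- TRUE
      }
    }
  }
  r <- rle(covered)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths
  cbind(lo[r$values], hi[r$values])
}

# per-base overlap of one region with the union of annotation intervals
bf_overlap_bp <- function(reg_start0, reg_end, ann_starts0, ann_ends) {
  if (!length(ann_starts0)) return(0)
  base <- logical(reg_end - reg_start0)
  for (i in seq_along(ann_starts0)) {
    lo <- max(ann_starts0[i], reg_start0)
    hi <- min(ann_ends[i], reg_end)
    if (lo < hi) base[(lo - reg_start0 + 1):(hi - reg_start0)] <- TRUE
  }
  sum(base)
}

# exhaustive optimal 2-means by enumerating all bipartitions
bf_best_2means <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(2^(0:(n - 1)), mask))
    if (!any(g) || all(g)) next
    wss <- 0
    for (sel in list(g, !g)) {
      xs <- x[sel, , drop = FALSE]
      mu <- colMeans(xs)
      wss <- wss + sum(sweep(xs, 2, mu)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

rand_track <- function(genome, bin_width, rfun = function(n) rpois(n, 5)) {
  vals <- lapply(stats::setNames(genome$length, genome$chrom),
                 function(L) as.numeric(rfun(ceiling(L / bin_width))))
  binned_track(genome, bin_width, vals)
}

rand_regions <- function(genome, n, min_len = 50, max_len = 600) {
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  maxl <- pmin(max_len, genome$length[ci])
  len <- min_len + floor(runif(n) * (maxl - min_len + 1))
  start0 <- floor(runif(n) * (genome$length[ci] - len + 1))
  gr0(genome$chrom[ci], start0, start0 + len)
}
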