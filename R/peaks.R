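#' Call broad peaks from a noise-reduced binned track
#'
#' Two-cutoff broad calling. (1) Strong segments are maximal runs of bins with
#' value >= `peak_cutoff`; strong segments shorter than `min_peak_length` bp
#' are discarded. (2) Weak segments are maximal runs of bins with value >=
#' `link_cutoff`; weak segments on the same chromosome separated by <=
#' `max_link_gap` bp are linked. (3) A broad peak is every linked weak segment
#' that contains at least one surviving strong segment; its coordinates are
#' the linked weak-segment bounds.
#'
#' The cutoff pairs used in the original analyses were 1000/500 for the
#' knockdown dataset and 850/425 for the sensitive/resistant dataset.
#'
#' @param track A [binned_track()] (typically IP minus input).
#' @param peak_cutoff Minimum bin value for a strong (core) segment.
#' @param link_cutoff Minimum bin value for a weak (linking) segment; must not
#'   exceed `peak_cutoff`.
#' @param min_peak_length Minimum strong-segment length in bp (default: one
#'   bin).
#' @param max_link_gap Maximum gap in bp across which weak segments are linked
#'   (default 800).
#' @return A sorted, non-overlapping `GRanges` of broad peaks.
#' @export
call_broad_peaks <- function(track, peak_cutoff, link_cutoff,
                             min_peak_length = NULL, max_link_gap = 800) {
  w <- track$bin_width
  if (is.null(min_peak_length)) min_peak_length <- w
  if (link_cutoff > peak_cutoff) {
    stop("call_broad_peaks: link_cutoff must be <= peak_cutoff")
  }
  if (min_peak_length < w) {
    stop("call_broad_peaks: min_peak_length must be >= bin_width")
  }
  if (max_link_gap < 0) stop("call_broad_peaks: max_link_gap must be >= 0")

  res <- list()
  for (k in seq_len(nrow(track$genome))) {
    chrom <- track$genome$chrom[k]
    L <- track$genome$length[k]
    v <- track$values[[k]]
    if (!length(v)) next
    weak <- run_bounds(v >= link_cutoff)
    if (!nrow(weak)) next
    strong <- run_bounds(v >= peak_cutoff)
    if (nrow(strong)) {
      # segment length in bp (last bin may be partial)
      s_bp <- pmin(strong$hi * w, L) - (strong$lo - 1) * w
      strong <- strong[s_bp >= min_peak_length, , drop = FALSE]
    }
    if (!nrow(strong)) next
    # link weak segments whose bp gap is <= max_link_gap
    start_bp <- (weak$lo - 1) * w
    end_bp <- pmin(weak$hi * w, L)
    grp <- cumsum(c(TRUE,
                    start_bp[-1L] - end_bp[-nrow(weak)] > max_link_gap))
    lstart <- tapply(start_bp, grp, min)
    lend <- tapply(end_bp, grp, max)
    # keep linked segments containing >= 1 surviving strong segment
    # (strong segments always lie inside weak ones since cutoffs are nested)
    s_bp0 <- (strong$lo - 1) * w
    keep <- vapply(seq_along(lstart), function(i) {
      any(s_bp0 >= lstart[i] & s_bp0 < lend[i])
    }, logical(1))
    if (!any(keep)) next
    res[[chrom]] <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = lstart[keep] + 1, end = lend[keep]))
  }
  if (!length(res)) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(gr) <- track$genome$chrom
    GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(track$genome)
    return(gr)
  }
  out <- sort(unlist(GenomicRanges::GRangesList(res), use.names = FALSE))
  validate_regions(out, track$genome)
}

# maximal TRUE runs of a logical vector: data.frame(lo, hi), 1-based inclusive
run_bounds <- function(flag) {
  r <- rle(flag)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  data.frame(lo = lo[r$values], hi = hi[r$values])
}

#' Union peak set across samples: concatenate, sort, merge, cluster
#'
#' Concatenates the per-sample peak sets, sorts by (chromosome order, start,
#' end), merges intervals whose gap is <= `merge_distance` bp (0 merges
#' overlapping and bookended intervals), and assigns consecutive integer
#' cluster ids in sorted order.
#'
#' @param peak_sets List of `GRanges` peak sets on one genome.
#' @param genome A [genome_model()].
#' @param merge_distance Maximum gap in bp for merging (default 0).
#' @return A sorted `GRanges` with a `cluster_id` metadata column.
#' @export
union_regions <- function(peak_sets, genome, merge_distance = 0) {
  if (merge_distance < 0) stop("union_regions: merge_distance must be >= 0")
  grl <- GenomicRanges::GRangesList(lapply(peak_sets, GenomicRanges::granges))
  gr <- unlist(grl, use.names = FALSE)
  gr <- validate_regions(gr, genome)
  merged <- GenomicRanges::reduce(sort(gr),
                                  min.gapwidth = merge_distance + 1)
  S4Vectors::mcols(merged)$cluster_id <- seq_along(merged)
  merged
}

#' Region size statistics
#'
#' @param regions Non-empty `GRanges`.
#' @return List with `n`, `mean_bp`, `median_bp`.
#' @export
region_size_stats <- function(regions) {
  if (length(regions) == 0L) stop("region_size_stats: empty region set")
  sz <- GenomicRanges::width(regions)
  list(n = length(sz), mean_bp = mean(sz), median_bp = stats::median(sz))
}
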