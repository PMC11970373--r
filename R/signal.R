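#' Bin per-base coverage of intervals into a fixed-width track
#'
#' Each interval contributes weight 1 per base; the value of a bin is the
#' total number of interval base pairs falling in it, so the sum over all
#' bins equals the total interval length.
#'
#' @param intervals A `GRanges` of intervals (e.g. read placements).
#' @param genome A [genome_model()].
#' @param bin_width Bin width in bp (default 200).
#' @return A [binned_track()].
#' @export
bin_coverage <- function(intervals, genome, bin_width = 200) {
  intervals <- validate_regions(intervals, genome)
  track <- binned_track(genome, bin_width)
  cov <- GenomicRanges::coverage(intervals)
  w <- track$bin_width
  for (k in seq_len(nrow(genome))) {
    chrom <- genome$chrom[k]
    L <- genome$length[k]
    starts <- seq(1, L, by = w)
    v <- IRanges::Views(cov[[chrom]], start = starts,
                        end = pmin(starts + w - 1, L))
    track$values[[chrom]] <- as.numeric(IRanges::viewSums(v))
  }
  track
}

#' Cross-sample quantile normalization of binned tracks
#'
#' Forces a common empirical distribution across samples: the reference
#' distribution is the element-wise mean of the samples' sorted genome-wide
#' value vectors; within each sample, the value of genome-wide rank r is
#' replaced by the rank-r reference value. Tied values all receive the mean of
#' the reference values over their tied rank span, which preserves each
#' sample's total signal. Normalization is genome-wide (one rank vector per
#' sample over all bins of all chromosomes); per-track bin order is preserved.
#'
#' IP and input samples should be normalized in separate calls; the pipeline
#' driver enforces this.
#'
#' @param tracks List of at least two [binned_track()]s sharing one genome and
#'   bin width.
#' @return List of normalized tracks, same order and names as the input.
#' @export
quantile_normalize <- function(tracks) {
  if (length(tracks) < 2L) {
    stop("quantile_normalize: at least two tracks are required")
  }
  if (!all(vapply(tracks, same_shape, logical(1), b = tracks[[1L]]))) {
    stop("quantile_normalize: tracks differ in genome or bin width")
  }
  mat <- vapply(tracks, track_flatten, numeric(sum(lengths(tracks[[1L]]$values))))
  ref <- rowMeans(apply(mat, 2L, sort, method = "quick"))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    o <- order(x)
    s <- x[o]
    # contiguous groups of tied values share the mean reference value
    grp <- cumsum(c(TRUE, s[-1L] != s[-length(s)]))
    norm_sorted <- stats::ave(ref, grp, FUN = mean)
    out[o, j] <- norm_sorted
  }
  res <- tracks
  for (j in seq_along(tracks)) {
    res[[j]] <- track_unflatten(tracks[[j]], out[, j])
  }
  res
}

#' Input subtraction ("noise reduction")
#'
#' Bin-wise difference IP - input. Negative values are retained, not clamped:
#' broad-peak cutoffs are far above zero, and clamping would silently alter
#' the signal matrices fed to clustering.
#'
#' @param ip,input [binned_track()]s with identical genome and bin width.
#' @return A [binned_track()] of differences.
#' @export
subtract_input <- function(ip, input) {
  if (!same_shape(ip, input)) {
    stop("subtract_input: tracks differ in genome or bin width")
  }
  ip$values <- Map(`-`, ip$values, input$values)
  ip
}

# bin-wise mean of several tracks (replicate averaging in the driver)
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  out <- tracks[[1L]]
  if (length(tracks) > 1L) {
    acc <- Reduce(function(a, b) Map(`+`, a, b), lapply(tracks, `[[`, "values"))
    out$values <- lapply(acc, `/`, length(tracks))
  }
  out
}

#' Sample sheet bundling binned tracks with their roles
#'
#' @param sample_id Unique sample identifiers.
#' @param role `"IP"` or `"input"` per sample.
#' @param condition Condition label per sample.
#' @param tracks List of [binned_track()]s, one per sample, sharing one genome
#'   and bin width.
#' @return A data.frame of class `track_set` with a `track` list-column.
#' @export
track_set <- function(sample_id, role, condition, tracks) {
  sample_id <- as.character(sample_id)
  role <- as.character(role)
  condition <- as.character(condition)
  if (anyDuplicated(sample_id)) stop("track_set: duplicate sample_id")
  if (!all(role %in% c("IP", "input"))) {
    stop("track_set: role must be 'IP' or 'input'")
  }
  if (length(tracks) != length(sample_id)) {
    stop("track_set: one track per sample required")
  }
  if (!all(vapply(tracks, same_shape, logical(1), b = tracks[[1L]]))) {
    stop("track_set: tracks differ in genome or bin width")
  }
  df <- data.frame(sample_id = sample_id, role = role, condition = condition,
                   stringsAsFactors = FALSE)
  df$track <- tracks
  class(df) <- c("track_set", "data.frame")
  df
}
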