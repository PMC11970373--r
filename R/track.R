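#' Binned signal track
#'
#' A fixed-width binned signal track over a [genome_model()]. Bin `i` (0-based)
#' of a chromosome of length `L` covers `[i*w, min((i+1)*w, L))`, so the last
#' bin may be partial; the number of bins is `ceiling(L / w)`.
#'
#' @param genome A `genome_model`.
#' @param bin_width Bin width in bp (default 200).
#' @param values Named list of numeric vectors, one per chromosome, or `NULL`
#'   for an all-zero track.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_width = 200, values = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  bin_width <- as.integer(bin_width)
  if (bin_width <= 0L) stop("binned_track: bin_width must be positive")
  nb <- n_bins_for(genome$length, bin_width)
  if (is.null(values)) {
    values <- lapply(nb, numeric)
    names(values) <- genome$chrom
  } else {
    if (!setequal(names(values), genome$chrom)) {
      stop("binned_track: values must be named by the genome's chromosomes")
    }
    values <- values[genome$chrom]
    got <- lengths(values)
    if (any(got != nb)) {
      stop("binned_track: wrong number of bins for ",
           paste(genome$chrom[got != nb], collapse = ", "))
    }
    if (any(!vapply(values, function(v) all(is.finite(v)), logical(1)))) {
      stop("binned_track: values must be finite")
    }
  }
  structure(list(genome = genome, bin_width = bin_width, values = values),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", sum(lengths(x$values)), "bins of", x$bin_width,
      "bp over", nrow(x$genome), "chromosome(s)\n")
  invisible(x)
}

# all bin values as one vector, chromosomes in genome order
track_flatten <- function(track) unlist(track$values, use.names = FALSE)

# inverse of track_flatten
track_unflatten <- function(track, v) {
  nb <- lengths(track$values)
  track$values <- stats::setNames(
    split(v, rep.int(seq_along(nb), nb)), names(track$values))
  track
}

same_shape <- function(a, b) {
  identical(a$genome$chrom, b$genome$chrom) &&
    identical(a$genome$length, b$genome$length) &&
    a$bin_width == b$bin_width
}

#' Read a bedGraph file into a binned track
#'
#' Intervals must align to the bin grid: start and end must be multiples of
#' `bin_width` (the end may instead equal the chromosome length, covering the
#' final partial bin). A line spanning several bins assigns its value to each
#' of them; uncovered bins are 0. Input intervals are assumed to partition the
#' covered positions (later lines overwrite earlier ones on overlap).
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; 0-based
#'   half-open, tab-separated, no header).
#' @param genome A `genome_model`.
#' @param bin_width Bin width in bp (default 200).
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, genome, bin_width = 200) {
  track <- binned_track(genome, bin_width)
  if (file.size(path) == 0) return(track)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df) == 0L) return(track)
  unknown <- setdiff(unique(df$chrom), genome$chrom)
  if (length(unknown)) {
    stop("read_bedgraph: unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  L <- chrom_length(genome, df$chrom)
  if (any(df$start < 0) || any(df$end > L)) {
    stop("read_bedgraph: interval beyond chromosome bounds")
  }
  if (any(df$start >= df$end)) stop("read_bedgraph: empty interval")
  w <- bin_width
  if (any(df$start %% w != 0) || any(df$end %% w != 0 & df$end != L)) {
    stop("read_bedgraph: interval not aligned to the ", w, "-bp bin grid")
  }
  b0 <- df$start %/% w                      # first bin, 0-based
  b1 <- as.integer(ceiling(df$end / w)) - 1L # last bin, 0-based
  nb <- b1 - b0 + 1L
  idx <- sequence(nb, from = b0 + 1L)       # 1-based bin indices
  ci <- rep.int(match(df$chrom, genome$chrom), nb)
  val <- rep.int(df$value, nb)
  for (k in unique(ci)) {
    sel <- ci == k
    track$values[[k]][idx[sel]] <- val[sel]
  }
  track
}

# shortest decimal representation that reads back to the same double
fmt_num <- function(x) {
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- format(x[bad], digits = 17, scientific = FALSE,
                                 trim = TRUE)
  s
}

#' Write a binned track as bedGraph
#'
#' All bins are emitted (including zeros) so that
#' `read_bedgraph(write_bedgraph(t))` reproduces `t` exactly.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @param merge_equal Emit maximal runs of equal-valued adjacent bins as one
#'   line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, merge_equal = TRUE) {
  w <- track$bin_width
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(track$genome))) {
    chrom <- track$genome$chrom[k]
    L <- track$genome$length[k]
    v <- track$values[[k]]
    if (!length(v)) next
    if (merge_equal) {
      r <- rle(v)
      hi <- cumsum(r$lengths)
      lo <- hi - r$lengths
      starts <- lo * w
      ends <- pmin(hi * w, L)
      vals <- r$values
    } else {
      starts <- (seq_along(v) - 1) * w
      ends <- pmin(seq_along(v) * w, L)
      vals <- v
    }
    writeLines(paste(chrom, fmt_num(starts), fmt_num(ends), fmt_num(vals),
                     sep = "\t"), con)
  }
  invisible(path)
}
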