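#' Genome model: an ordered set of chromosomes with lengths
#'
#' A `genome_model` is the coordinate universe for every track and interval in
#' the package. Chromosome order is preserved from construction (or file
#' order) and defines output order everywhere downstream.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of positive integer chromosome lengths (bp).
#' @return An object of class `genome_model`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' gm <- genome_model(c("chrA", "chrB"), c(10000, 5000))
#' chrom_length(gm, "chrB")
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) {
    stop("genome_model: at least one chromosome is required")
  }
  if (length(chrom) != length(length)) {
    stop("genome_model: 'chrom' and 'length' differ in length")
  }
  if (anyDuplicated(chrom)) {
    stop("genome_model: duplicate chromosome name(s): ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("genome_model: chromosome lengths must be positive integers")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model with", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Length of one chromosome
#' @param genome A `genome_model`.
#' @param chrom Chromosome name.
#' @return Length in bp.
#' @export
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ", paste(chrom[is.na(i)], collapse = ", "))
  }
  genome$length[i]
}

#' Seqinfo view of a genome model
#'
#' Used to stamp `GRanges` objects so that coordinate validation and trimming
#' follow the genome model.
#' @param genome A `genome_model`.
#' @return A [GenomeInfoDb::Seqinfo] with the model's chromosomes in order.
#' @export
genome_seqinfo <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  GenomeInfoDb::Seqinfo(seqnames = genome$chrom, seqlengths = genome$length)
}

# number of fixed-width bins per chromosome (last bin may be partial)
n_bins_for <- function(L, bin_width) as.integer(ceiling(L / bin_width))

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name and integer length, no header.
#'
#' @param path Path to a chrom.sizes file.
#' @return A [genome_model()] in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("read_chrom_sizes: empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("read_chrom_sizes: expected two tab-separated columns")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  len_chr <- vapply(parts, `[[`, character(1), 2L)
  if (any(!grepl("^[0-9]+$", len_chr))) {
    stop("read_chrom_sizes: non-integer chromosome length")
  }
  genome_model(chrom, as.numeric(len_chr))
}

#' Validate a set of regions against a genome model
#'
#' Checks that all seqnames exist in the model and that coordinates lie within
#' chromosome bounds. Regions follow the Bioconductor convention (1-based,
#' closed); BED I/O converts from/to 0-based half-open at the file boundary.
#'
#' @param gr A `GRanges`.
#' @param genome A `genome_model`.
#' @return `gr`, invisibly, with seqinfo set from the model.
#' @export
validate_regions <- function(gr, genome) {
  sn <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(sn), genome$chrom)
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  L <- chrom_length(genome, sn)
  if (any(GenomicRanges::start(gr) < 1) || any(GenomicRanges::end(gr) > L)) {
    stop("region(s) outside chromosome bounds")
  }
  GenomeInfoDb::seqlevels(gr) <- genome$chrom
  GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
  invisible(gr)
}

# internal: GRanges from 0-based half-open coordinates
gr_from_bed0 <- function(chrom, start0, end, genome, strand = NULL) {
  if (any(start0 >= end)) stop("empty or inverted interval (start >= end)")
  if (any(start0 < 0)) stop("negative start coordinate")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end),
    strand = if (is.null(strand)) "*" else strand
  )
  validate_regions(gr, genome)
}
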