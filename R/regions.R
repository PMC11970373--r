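#' Read a BED file (BED3+) into a GRanges
#'
#' Coordinates are converted from BED's 0-based half-open convention to the
#' Bioconductor 1-based closed convention. Optional columns 4-6 become the
#' `name` and `score` metadata columns and the strand (`.` maps to `*`).
#' Rows keep file order.
#'
#' @param path Path to a BED file.
#' @param genome A [genome_model()] used to validate coordinates.
#' @return A `GRanges` with optional `name`/`score` metadata columns.
#' @export
read_bed <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = FALSE)
  if (ncol(df) < 3L) stop("read_bed: expected at least 3 columns")
  strand <- NULL
  if (ncol(df) >= 6L) {
    strand <- df[[6L]]
    strand[strand == "."] <- "*"
    if (!all(strand %in% c("+", "-", "*"))) {
      stop("read_bed: invalid strand value")
    }
  }
  gr <- gr_from_bed0(df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]),
                     genome, strand = strand)
  if (ncol(df) >= 4L) S4Vectors::mcols(gr)$name <- df[[4L]]
  if (ncol(df) >= 5L) {
    sc <- df[[5L]]
    S4Vectors::mcols(gr)$score <- ifelse(sc == ".", NA_real_,
                                         suppressWarnings(as.numeric(sc)))
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits 0-based half-open coordinates. `name`, `score` and strand columns are
#' written when present (missing values become `.`); `name_col` can redirect
#' the BED name field to another metadata column (e.g. a cluster id or a
#' gain/loss/common label).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name_col Metadata column to use as the BED name field (default
#'   `"name"`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name_col = "name") {
  mc <- S4Vectors::mcols(gr)
  cols <- list(
    as.character(GenomeInfoDb::seqnames(gr)),
    fmt_num(GenomicRanges::start(gr) - 1),
    fmt_num(GenomicRanges::end(gr))
  )
  has_name <- name_col %in% names(mc)
  has_score <- "score" %in% names(mc)
  st <- as.character(GenomicRanges::strand(gr))
  has_strand <- any(st != "*")
  if (has_name || has_score || has_strand) {
    nm <- if (has_name) as.character(mc[[name_col]]) else rep(".", length(gr))
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
  }
  if (has_score || has_strand) {
    sc <- if (has_score) ifelse(is.na(mc$score), ".", fmt_num(mc$score))
          else rep(".", length(gr))
    cols <- c(cols, list(sc))
  }
  if (has_strand) {
    st[st == "*"] <- "."
    cols <- c(cols, list(st))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a RepeatMasker-style BED of repeat elements
#'
#' Two layouts are supported. In the `"columns"` dialect the repeat class and
#' subfamily occupy two extra columns after the standard BED6 fields
#' (chrom, start, end, name, score, strand, class, subfamily). In the
#' `"slash"` dialect a single extra column holds `class/subfamily`, split on
#' the first `/`; a value with no `/` (e.g. `Satellite`) yields
#' subfamily = class. Class strings containing `?` are kept literally.
#'
#' @param path Path to the repeat BED.
#' @param genome A [genome_model()].
#' @param dialect `"columns"` or `"slash"`.
#' @return A `GRanges` with metadata columns `repeat_name`, `repeat_class`,
#'   `repeat_subfamily`.
#' @export
read_repeat_bed <- function(path, genome, dialect = c("columns", "slash")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = FALSE)
  need <- if (dialect == "columns") 8L else 7L
  if (ncol(df) < need) {
    stop("read_repeat_bed: missing repeat class column (need ", need,
         " columns for the '", dialect, "' dialect)")
  }
  strand <- df[[6L]]
  strand[strand == "."] <- "*"
  gr <- gr_from_bed0(df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]),
                     genome, strand = strand)
  if (dialect == "columns") {
    cls <- df[[7L]]
    sub <- df[[8L]]
  } else {
    cf <- df[[7L]]
    slash <- regexpr("/", cf, fixed = TRUE)
    cls <- ifelse(slash > 0L, substr(cf, 1L, slash - 1L), cf)
    sub <- ifelse(slash > 0L, substring(cf, slash + 1L), cf)
  }
  if (any(!nzchar(cls))) stop("read_repeat_bed: empty repeat class")
  sub[!nzchar(sub)] <- cls[!nzchar(sub)]
  S4Vectors::mcols(gr)$repeat_name <- df[[4L]]
  S4Vectors::mcols(gr)$repeat_class <- cls
  S4Vectors::mcols(gr)$repeat_subfamily <- sub
  gr
}

#' Write repeat elements as a RepeatMasker-style BED (columns dialect)
#'
#' @param repeats A `GRanges` with `repeat_name`, `repeat_class`,
#'   `repeat_subfamily` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(repeats, path) {
  mc <- S4Vectors::mcols(repeats)
  st <- as.character(GenomicRanges::strand(repeats))
  st[st == "*"] <- "."
  writeLines(paste(
    as.character(GenomeInfoDb::seqnames(repeats)),
    fmt_num(GenomicRanges::start(repeats) - 1),
    fmt_num(GenomicRanges::end(repeats)),
    as.character(mc$repeat_name), ".", st,
    as.character(mc$repeat_class), as.character(mc$repeat_subfamily),
    sep = "\t"), path)
  invisible(path)
}

#' Extract deduplicated promoter windows around transcription start sites
#'
#' The TSS of a `+` feature is its start, of a `-` feature its end. The
#' promoter is the window of `flank` bp on both sides of the TSS, clipped at
#' chromosome bounds, so its width is `2 * flank` except at chromosome ends.
#' Exact duplicate intervals (same chromosome, start and end, regardless of
#' strand) are removed and the result is sorted in genome order.
#'
#' @param genes Stranded `GRanges` of genes/transcripts (every element must be
#'   on `+` or `-`).
#' @param genome A [genome_model()].
#' @param flank Half-width of the promoter window in bp (default 1000).
#' @return An unstranded, sorted, duplicate-free `GRanges` of promoters.
#' @export
extract_promoters <- function(genes, genome, flank = 1000) {
  if (flank <= 0) stop("extract_promoters: flank must be positive")
  st <- as.character(GenomicRanges::strand(genes))
  if (any(st == "*")) stop("extract_promoters: unstranded gene(s)")
  genes <- validate_regions(genes, genome)
  # out-of-bound windows at chromosome ends are expected; trim() clips them
  prom <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = flank, downstream = flank))
  prom <- GenomicRanges::trim(prom)
  prom <- prom[GenomicRanges::width(prom) > 0]
  prom <- GenomicRanges::granges(prom)  # drop mcols
  GenomicRanges::strand(prom) <- "*"
  sort(unique(prom))
}
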