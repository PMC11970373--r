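#' Simulation configuration for synthetic differential-heterochromatin data
#'
#' The defaults define the study conditions used throughout the test suite:
#' a 2 x 2 Mb genome binned at 200 bp; a repeat catalogue with classes LTR
#' (subfamilies ERV1, ERVL, ERVL-MalR), SINE (Alu, MIR) and a NEUTRAL class
#' (a Satellite entry is specified but drawn with count 0 by default);
#' 30 common, 20 gain and 20 loss domains of 600-3000 bp; differential
#' domains anchored on LTR elements with probability `p_enrich = 0.8`;
#' Poisson bin counts with background mean 20, input mean 20 and +60 signal
#' units inside active domains (far above half the domain amplitude, so peak
#' calling is not operated near its decision boundary).
#'
#' @param seed Integer seed driving all randomness.
#' @param genome data.frame with `chrom`, `length` columns or a
#'   [genome_model()].
#' @param bin_width Bin width in bp (default 200).
#' @param repeats data.frame with columns `class`, `subfamily`, `count`,
#'   `min_len`, `max_len` (uniform integer length distribution).
#' @param n_common,n_gain,n_loss Domain counts per label.
#' @param domain_min_len,domain_max_len Domain length bounds in bp.
#' @param target_class Named character: repeat class on which `gain` / `loss`
#'   domains are anchored.
#' @param p_enrich Probability that a differential domain is centred on an
#'   element of its target class (otherwise placed uniformly).
#' @param lambda_bg Background IP Poisson mean per bin.
#' @param fold Signal units added per bin inside an active domain.
#' @param lambda_input Input Poisson mean per bin.
#' @param conditions Character vector of two condition labels; gain domains
#'   are active only in the second, loss domains only in the first, common
#'   domains in both.
#' @param replicates IP/input replicate pairs per condition.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = data.frame(
                         chrom = c("chr1", "chr2"),
                         length = c(2e6, 2e6)),
                       bin_width = 200,
                       repeats = data.frame(
                         class = c("LTR", "LTR", "LTR", "SINE", "SINE",
                                   "Satellite", "NEUTRAL"),
                         subfamily = c("ERV1", "ERVL", "ERVL-MalR", "Alu",
                                       "MIR", "Satellite", "NEUTRAL"),
                         count = c(100, 100, 150, 400, 250, 0, 300),
                         min_len = c(300, 300, 300, 250, 100, 2000, 200),
                         max_len = c(800, 800, 800, 350, 250, 8000, 500),
                         stringsAsFactors = FALSE),
                       n_common = 30, n_gain = 20, n_loss = 20,
                       domain_min_len = 600, domain_max_len = 3000,
                       target_class = c(gain = "LTR", loss = "LTR"),
                       p_enrich = 0.8,
                       lambda_bg = 20, fold = 60, lambda_input = 20,
                       conditions = c("A", "B"), replicates = 1) {
  if (!inherits(genome, "genome_model")) {
    genome <- genome_model(genome$chrom, genome$length)
  }
  if (p_enrich < 0 || p_enrich > 1) stop("sim_config: p_enrich must be in [0,1]")
  if (lambda_bg <= 0 || lambda_input <= 0 || fold < 0) {
    stop("sim_config: signal means must be positive")
  }
  if (length(conditions) != 2L) {
    stop("sim_config: exactly two conditions are supported")
  }
  structure(list(
    seed = seed, genome = genome, bin_width = bin_width, repeats = repeats,
    n_common = n_common, n_gain = n_gain, n_loss = n_loss,
    domain_min_len = domain_min_len, domain_max_len = domain_max_len,
    target_class = target_class, p_enrich = p_enrich,
    lambda_bg = lambda_bg, fold = fold, lambda_input = lambda_input,
    conditions = conditions, replicates = replicates
  ), class = "sim_config")
}

# uniform integer in [lo, hi], vectorized, from the current RNG stream
runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# uniform placement of n intervals of the given lengths: chromosome drawn
# with probability proportional to valid start positions, start uniform
place_uniform <- function(n, len, genome) {
  vn <- outer(genome$length, len, function(L, l) pmax(L - l + 1, 0))
  vn <- matrix(vn, nrow = nrow(genome))
  tot <- colSums(vn)
  if (any(tot == 0)) stop("interval longer than every chromosome")
  cp <- apply(vn, 2L, cumsum)
  if (is.null(dim(cp))) cp <- matrix(cp, nrow = 1L)
  u <- stats::runif(n) * tot
  ci <- colSums(cp < matrix(u, nrow = nrow(cp), ncol = n, byrow = TRUE)) + 1L
  start0 <- floor(stats::runif(n) * vn[cbind(ci, seq_len(n))])
  GenomicRanges::GRanges(
    seqnames = genome$chrom[ci],
    ranges = IRanges::IRanges(start = start0 + 1, width = len))
}

#' Simulate a repeat catalogue
#'
#' For each configured (class, subfamily) row, draws the configured number of
#' elements with uniform integer lengths and uniform placement; overlaps are
#' permitted. Consumes the current RNG stream.
#'
#' @param config A [sim_config()].
#' @return `GRanges` with `repeat_name`, `repeat_class`, `repeat_subfamily`.
#' @export
simulate_repeats <- function(config) {
  rs <- config$repeats
  parts <- list()
  for (i in seq_len(nrow(rs))) {
    n <- rs$count[i]
    if (n == 0) next
    len <- runif_int(n, rs$min_len[i], rs$max_len[i])
    gr <- place_uniform(n, len, config$genome)
    S4Vectors::mcols(gr)$repeat_name <- paste0(rs$subfamily[i], "_",
                                               seq_len(n))
    S4Vectors::mcols(gr)$repeat_class <- rs$class[i]
    S4Vectors::mcols(gr)$repeat_subfamily <- rs$subfamily[i]
    parts[[length(parts) + 1L]] <- gr
  }
  if (!length(parts)) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(config$genome)
    S4Vectors::mcols(gr)$repeat_name <- character(0)
    S4Vectors::mcols(gr)$repeat_class <- character(0)
    S4Vectors::mcols(gr)$repeat_subfamily <- character(0)
    return(gr)
  }
  out <- unlist(GenomicRanges::GRangesList(parts), use.names = FALSE)
  validate_regions(out, config$genome)
}

#' Simulate planted heterochromatin domains (the truth table)
#'
#' Common domains are placed uniformly. Each differential (gain/loss) domain
#' is, with probability `p_enrich`, centred on the midpoint of a uniformly
#' chosen element of its target repeat class, otherwise placed uniformly;
#' domains are clipped to chromosome bounds. Consumes the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param repeats Catalogue from [simulate_repeats()].
#' @return `GRanges` truth table with metadata `label` in
#'   `{common, gain, loss}` and `anchor_class` (`NA` when placed uniformly).
#' @export
simulate_domains <- function(config, repeats) {
  labels <- rep(c("common", "gain", "loss"),
                c(config$n_common, config$n_gain, config$n_loss))
  n <- length(labels)
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(config$genome)
    S4Vectors::mcols(gr)$label <- character(0)
    S4Vectors::mcols(gr)$anchor_class <- character(0)
    return(gr)
  }
  len <- runif_int(n, config$domain_min_len, config$domain_max_len)
  placed <- place_uniform(n, len, config$genome)
  anchor <- rep(NA_character_, n)
  cls <- S4Vectors::mcols(repeats)$repeat_class
  for (i in seq_len(n)) {
    lb <- labels[i]
    if (!lb %in% names(config$target_class)) next
    tc <- config$target_class[[lb]]
    if (stats::runif(1) >= config$p_enrich) next
    cand <- which(cls == tc)
    if (!length(cand)) stop("simulate_domains: anchored class '", tc,
                            "' absent from catalogue")
    el <- repeats[cand[runif_int(1L, 1L, length(cand))]]
    mid0 <- (GenomicRanges::start(el) - 1 + GenomicRanges::end(el)) %/% 2
    s0 <- mid0 - len[i] %/% 2
    L <- chrom_length(config$genome,
                      as.character(GenomeInfoDb::seqnames(el)))
    s0 <- max(0, min(s0, L - 1))
    e0 <- min(L, s0 + len[i])
    placed[i] <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(el),
      ranges = IRanges::IRanges(start = s0 + 1, end = e0))
    anchor[i] <- tc
  }
  S4Vectors::mcols(placed)$label <- labels
  S4Vectors::mcols(placed)$anchor_class <- anchor
  validate_regions(placed, config$genome)
}

#' Simulate IP and input tracks with planted domain signal
#'
#' Input bins are Poisson(`lambda_input`). IP bins are
#' Poisson(`lambda_bg` + `fold` * active), where a bin is active when it
#' overlaps a domain active in the sample's condition: common domains in all
#' conditions, gain domains only in the second condition, loss domains only
#' in the first. Bins and samples are independent. Consumes the current RNG
#' stream.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_domains()].
#' @return A [track_set()] with one IP and one input sample per
#'   condition x replicate.
#' @export
simulate_tracks <- function(config, truth) {
  genome <- config$genome
  w <- config$bin_width
  labels <- S4Vectors::mcols(truth)$label
  active_domains <- list()
  active_domains[[config$conditions[1L]]] <-
    truth[labels %in% c("common", "loss")]
  active_domains[[config$conditions[2L]]] <-
    truth[labels %in% c("common", "gain")]

  # bins overlapping an active domain, as a logical per chromosome
  active_bins <- function(domains) {
    lapply(seq_len(nrow(genome)), function(k) {
      L <- genome$length[k]
      nb <- n_bins_for(L, w)
      act <- logical(nb)
      d <- domains[as.character(GenomeInfoDb::seqnames(domains)) ==
                     genome$chrom[k]]
      if (length(d)) {
        k0 <- (GenomicRanges::start(d) - 1) %/% w
        k1 <- ceiling(GenomicRanges::end(d) / w) - 1
        for (j in seq_along(d)) act[(k0[j]:k1[j]) + 1] <- TRUE
      }
      act
    })
  }

  ids <- character(0); roles <- character(0); conds <- character(0)
  tracks <- list()
  for (cond in config$conditions) {
    act <- active_bins(active_domains[[cond]])
    lam_ip <- lapply(act, function(a) config$lambda_bg + config$fold * a)
    for (r in seq_len(config$replicates)) {
      ip_vals <- lapply(lam_ip, function(lam) as.numeric(stats::rpois(
        length(lam), lam)))
      in_vals <- lapply(lengths(lam_ip), function(nb) as.numeric(stats::rpois(
        nb, config$lambda_input)))
      names(ip_vals) <- genome$chrom
      names(in_vals) <- genome$chrom
      ids <- c(ids, paste0(cond, "_rep", r, "_IP"),
               paste0(cond, "_rep", r, "_input"))
      roles <- c(roles, "IP", "input")
      conds <- c(conds, cond, cond)
      tracks <- c(tracks,
                  list(binned_track(genome, w, ip_vals),
                       binned_track(genome, w, in_vals)))
    }
  }
  track_set(ids, roles, conds, tracks)
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG from `config$seed` and draws, in order, the repeat
#' catalogue, the domain truth table and the IP/input tracks. Bit-reproducible
#' for a fixed config.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome`, `repeats`, `truth`, `tracks`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  with_seed(config$seed, {
    repeats <- simulate_repeats(config)
    truth <- simulate_domains(config, repeats)
    tracks <- simulate_tracks(config, truth)
    list(config = config, genome = config$genome, repeats = repeats,
         truth = truth, tracks = tracks)
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `chrom.sizes`, `repeats.bed` (columns dialect), one bedGraph per
#' sample (`<sample_id>.bedgraph`), `truth.tsv` and a `samples.tsv` sheet.
#' [read_dataset()] reproduces the objects.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- dataset$genome
  writeLines(paste(gm$chrom, fmt_num(gm$length), sep = "\t"),
             file.path(out_dir, "chrom.sizes"))
  write_repeat_bed(dataset$repeats, file.path(out_dir, "repeats.bed"))
  tr <- dataset$truth
  truth_df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tr)),
    start = GenomicRanges::start(tr) - 1,
    end = GenomicRanges::end(tr),
    label = S4Vectors::mcols(tr)$label,
    anchor_class = ifelse(is.na(S4Vectors::mcols(tr)$anchor_class), ".",
                          S4Vectors::mcols(tr)$anchor_class))
  utils::write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ts <- dataset$tracks
  for (i in seq_len(nrow(ts))) {
    write_bedgraph(ts$track[[i]],
                   file.path(out_dir, paste0(ts$sample_id[i], ".bedgraph")))
  }
  utils::write.table(
    data.frame(sample_id = ts$sample_id, role = ts$role,
               condition = ts$condition,
               path = paste0(ts$sample_id, ".bedgraph")),
    file.path(out_dir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(out_dir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Directory written by [write_dataset()].
#' @param bin_width Bin width in bp (default 200).
#' @return List with `genome`, `repeats`, `truth`, `tracks`.
#' @export
read_dataset <- function(dir, bin_width = 200) {
  genome <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  repeats <- read_repeat_bed(file.path(dir, "repeats.bed"), genome,
                             dialect = "columns")
  td <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                          header = TRUE, colClasses = c(
                            "character", "numeric", "numeric", "character",
                            "character"))
  truth <- if (nrow(td)) {
    gr <- gr_from_bed0(td$chrom, td$start, td$end, genome)
    S4Vectors::mcols(gr)$label <- td$label
    S4Vectors::mcols(gr)$anchor_class <- ifelse(td$anchor_class == ".",
                                                NA_character_,
                                                td$anchor_class)
    gr
  } else {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
    gr
  }
  sh <- utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                          header = TRUE, colClasses = "character")
  tracks <- lapply(sh$path, function(p)
    read_bedgraph(file.path(dir, p), genome, bin_width))
  list(genome = genome, repeats = repeats, truth = truth,
       tracks = track_set(sh$sample_id, sh$role, sh$condition, tracks))
}
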