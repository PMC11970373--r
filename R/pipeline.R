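#' Run the full differential-heterochromatin pipeline
#'
#' Stages, in order: (1) quantile-normalize IP samples and input samples as
#' two separate groups; (2) noise reduction: per sample, subtract the matched
#' input from the IP track, then average replicates per condition; (3) call
#' broad peaks per condition on the noise-reduced tracks; (4) build the
#' clustered union peak set; (5) extract the peak-centred signal matrix from
#' the noise-reduced tracks; (6) k-means-cluster the matrix and label
#' clusters gain/loss/common between the two conditions; (7) annotate the
#' union regions against repeats (and promoters when genes are supplied) and
#' compute the shuffle-based observed/expected enrichment of the differential
#' regions by repeat class and subfamily.
#'
#' One global `seed` deterministically derives per-stage seeds, so reruns are
#' byte-identical and stages can be reproduced in isolation.
#'
#' @param samples A [track_set()]; every condition needs at least one IP and
#'   one input sample.
#' @param repeats Repeat catalogue `GRanges` ([read_repeat_bed()]), or `NULL`
#'   to skip enrichment.
#' @param genes Stranded gene `GRanges` for promoter association, or `NULL`.
#' @param peak_cutoff,link_cutoff Broad-peak cutoffs (see
#'   [call_broad_peaks()]).
#' @param min_peak_length,max_link_gap Peak-caller geometry parameters.
#' @param merge_distance Union merge distance in bp (default 0).
#' @param window,n_bins Signal-matrix geometry (default 10 kb / 50 bins).
#' @param k Number of k-means clusters (default 4: one per expected class
#'   plus one, so a heterogeneous class can split without stealing another
#'   class's cluster; labelling re-merges clusters of equal label).
#' @param row_normalize Row normalization passed to [kmeans_cluster()]
#'   (default `"l2"`).
#' @param n_init K-means restarts in the driver (default 100; restarts are
#'   cheap at pipeline scale and the best-inertia solution is kept).
#' @param fold_threshold Gain/loss fold threshold (default 1.5).
#' @param flank Promoter half-width in bp (default 1000).
#' @param n_shuffles,n_empirical Enrichment shuffle counts (defaults 3 / 0).
#' @param seed Global integer seed (default 1).
#' @param out_dir If non-`NULL`, write result files (BEDs, TSVs,
#'   `summary.json`) into this directory.
#' @return List with the per-stage results: `normalized`, `noise_reduced`,
#'   `peaks`, `union`, `matrix`, `clustering`, `labels` (per-region),
#'   `cluster_labels`, `enrichment_class`, `enrichment_subfamily`,
#'   `promoters`, `summary`.
#' @export
run_pipeline <- function(samples, repeats = NULL, genes = NULL,
                         peak_cutoff, link_cutoff,
                         min_peak_length = NULL, max_link_gap = 800,
                         merge_distance = 0, window = 10000, n_bins = 50,
                         k = 4, row_normalize = "l2", n_init = 100,
                         fold_threshold = 1.5, flank = 1000,
                         n_shuffles = 3, n_empirical = 0,
                         seed = 1, out_dir = NULL) {
  stopifnot(inherits(samples, "track_set"))
  genome <- samples$track[[1L]]$genome
  conditions <- unique(samples$condition)
  if (length(conditions) != 2L) {
    stop("run_pipeline: exactly two conditions are required")
  }
  for (cond in conditions) {
    sel <- samples$condition == cond
    if (!any(samples$role[sel] == "IP") || !any(samples$role[sel] == "input")) {
      stop("run_pipeline: condition '", cond,
           "' lacks an IP or an input sample")
    }
  }

  # (1) quantile normalization, IP and input separately
  ip_idx <- which(samples$role == "IP")
  in_idx <- which(samples$role == "input")
  norm <- samples$track
  if (length(ip_idx) >= 2L) norm[ip_idx] <- quantile_normalize(norm[ip_idx])
  if (length(in_idx) >= 2L) norm[in_idx] <- quantile_normalize(norm[in_idx])

  # (2) noise reduction per IP sample, then replicate averaging per condition
  noise_reduced <- list()
  for (cond in conditions) {
    ips <- which(samples$condition == cond & samples$role == "IP")
    ins <- which(samples$condition == cond & samples$role == "input")
    nr <- lapply(seq_along(ips), function(i) {
      subtract_input(norm[[ips[i]]], norm[[ins[min(i, length(ins))]]])
    })
    noise_reduced[[cond]] <- average_tracks(nr)
  }

  # (3) broad peaks per condition
  peaks <- lapply(noise_reduced, call_broad_peaks,
                  peak_cutoff = peak_cutoff, link_cutoff = link_cutoff,
                  min_peak_length = min_peak_length,
                  max_link_gap = max_link_gap)

  # (4) union peak set
  union <- union_regions(peaks, genome, merge_distance = merge_distance)
  if (length(union) < k) {
    stop("run_pipeline: fewer union regions (", length(union),
         ") than clusters (k = ", k, ")")
  }

  # (5) signal matrix around peak centres
  sm <- extract_signal_matrix(noise_reduced, union, window = window,
                              n_bins = n_bins)

  # (6) k-means and gain/loss/common labelling
  clust <- kmeans_cluster(sm, k = k, seed = stage_seed(seed, "kmeans"),
                          n_init = n_init, row_normalize = row_normalize)
  cm <- cluster_condition_means(sm, clust$assignment)
  cluster_labels <- classify_clusters(cm[, conditions[1L]],
                                      cm[, conditions[2L]],
                                      fold_threshold = fold_threshold)
  names(cluster_labels) <- rownames(cm)
  labels <- cluster_labels[as.character(clust$assignment)]
  names(labels) <- names(clust$assignment)
  S4Vectors::mcols(union)$cluster <- clust$assignment
  S4Vectors::mcols(union)$label <- unname(labels)

  # (7) association and enrichment
  promoters <- NULL
  pct_promoter <- NULL
  if (!is.null(genes)) {
    promoters <- extract_promoters(genes, genome, flank = flank)
    pct_promoter <- vapply(split(union, S4Vectors::mcols(union)$label),
                           percent_associated, numeric(1),
                           annotation = promoters)
  }
  enrichment_class <- NULL
  enrichment_subfamily <- NULL
  pct_repeat <- NULL
  if (!is.null(repeats)) {
    pct_repeat <- vapply(split(union, S4Vectors::mcols(union)$label),
                         percent_associated, numeric(1), annotation = repeats)
    differential <- union[S4Vectors::mcols(union)$label %in% c("gain", "loss")]
    if (length(differential)) {
      enrichment_class <- obs_exp_enrichment(
        differential, repeats, genome, grouping = "class",
        n_shuffles = n_shuffles, seed = stage_seed(seed, "enrich_class"),
        n_empirical = n_empirical)
      enrichment_subfamily <- obs_exp_enrichment(
        differential, repeats, genome, grouping = "subfamily",
        n_shuffles = n_shuffles, seed = stage_seed(seed, "enrich_subfamily"),
        n_empirical = n_empirical)
    }
  }

  sizes <- lapply(split(union, S4Vectors::mcols(union)$label),
                  region_size_stats)
  summary <- list(
    n_regions = length(union),
    n_peaks_per_condition = vapply(peaks, length, integer(1)),
    region_sizes_by_label = sizes,
    cluster_labels = as.list(cluster_labels),
    pct_repeat_associated_by_label = as.list(pct_repeat),
    pct_promoter_associated_by_label = as.list(pct_promoter)
  )

  result <- list(normalized = norm, noise_reduced = noise_reduced,
                 peaks = peaks, union = union, matrix = sm,
                 clustering = clust, labels = labels,
                 cluster_labels = cluster_labels,
                 enrichment_class = enrichment_class,
                 enrichment_subfamily = enrichment_subfamily,
                 promoters = promoters, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in conditions) {
      write_bed(peaks[[cond]],
                file.path(out_dir, paste0("peaks_", cond, ".bed")))
    }
    u <- union
    S4Vectors::mcols(u)$name <- paste0(S4Vectors::mcols(u)$cluster_id, "_",
                                       S4Vectors::mcols(u)$label)
    write_bed(u, file.path(out_dir, "union.bed"))
    write_signal_matrix(sm, file.path(out_dir, "matrix.tsv"))
    if (!is.null(enrichment_class)) {
      utils::write.table(enrichment_class,
                         file.path(out_dir, "enrichment_class.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment_subfamily)) {
      utils::write.table(enrichment_subfamily,
                         file.path(out_dir, "enrichment_subfamily.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
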