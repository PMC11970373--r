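#' Extract a peak-centred signal matrix per condition
#'
#' For each region the window of `window` bp centred on
#' `floor((start0 + end0) / 2)` (0-based midpoint) is split into `n_bins`
#' equal matrix bins; the value of a matrix bin is the mean of the underlying
#' track bins overlapping it, with portions beyond chromosome ends counted as
#' 0. With the defaults (10 kb window, 50 bins) each matrix bin spans exactly
#' one 200-bp track bin.
#'
#' @param tracks Named list of [binned_track()]s, one per condition (noise
#'   reduced; replicates averaged upstream).
#' @param regions `GRanges` of regions (typically the union peak set).
#' @param window Window width in bp (default 10000); must be divisible by
#'   `n_bins`, and `window / n_bins` by the track bin width.
#' @param n_bins Number of matrix bins (default 50).
#' @return An object of class `signal_matrix`: list with `region_id`,
#'   `conditions`, and `mat` (named list of n_regions x n_bins matrices).
#' @export
extract_signal_matrix <- function(tracks, regions, window = 10000,
                                  n_bins = 50) {
  stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
  w <- tracks[[1L]]$bin_width
  if (!all(vapply(tracks, same_shape, logical(1), b = tracks[[1L]]))) {
    stop("extract_signal_matrix: tracks differ in genome or bin width")
  }
  if (window %% n_bins != 0) {
    stop("extract_signal_matrix: window must be divisible by n_bins")
  }
  mb <- window %/% n_bins
  if (mb %% w != 0) {
    stop("extract_signal_matrix: window/n_bins must be divisible by bin_width")
  }
  genome <- tracks[[1L]]$genome
  regions <- validate_regions(regions, genome)
  ids <- if (!is.null(S4Vectors::mcols(regions)$cluster_id)) {
    S4Vectors::mcols(regions)$cluster_id
  } else {
    seq_along(regions)
  }
  k_per <- mb %/% w  # track bins per matrix bin
  n_reg <- length(regions)
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  start0 <- GenomicRanges::start(regions) - 1
  end0 <- GenomicRanges::end(regions)
  centre <- (start0 + end0) %/% 2
  win_start <- centre - window %/% 2

  mats <- lapply(tracks, function(tr) {
    m <- matrix(0, nrow = n_reg, ncol = n_bins)
    for (i in seq_len(n_reg)) {
      v <- tr$values[[chrom[i]]]
      nb <- length(v)
      # track bins overlapping each matrix bin
      mstarts <- win_start[i] + (seq_len(n_bins) - 1) * mb
      for (j in seq_len(n_bins)) {
        k0 <- floor(mstarts[j] / w)
        k1 <- ceiling((mstarts[j] + mb) / w) - 1
        ks <- k0:k1
        vals <- ifelse(ks >= 0 & ks < nb, v[pmax(ks, 0) + 1], 0)
        vals[ks < 0 | ks >= nb] <- 0
        m[i, j] <- mean(vals)
      }
    }
    rownames(m) <- as.character(ids)
    m
  })
  structure(list(region_id = ids, conditions = names(tracks), mat = mats),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", length(x$region_id), "regions x",
      ncol(x$mat[[1L]]), "bins x", length(x$conditions), "condition(s) (",
      paste(x$conditions, collapse = ", "), ")\n")
  invisible(x)
}

#' Export a signal matrix as TSV
#'
#' One row per region: region id followed by the per-condition bin columns
#' (`<condition>_bin<j>`).
#'
#' @param sm A [extract_signal_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(sm, path) {
  wide <- do.call(cbind, lapply(seq_along(sm$mat), function(i) {
    m <- sm$mat[[i]]
    colnames(m) <- paste0(sm$conditions[i], "_bin", seq_len(ncol(m)))
    m
  }))
  df <- data.frame(region_id = sm$region_id, wide, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# squared Euclidean distances between rows of x and rows of centers
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii); deterministic given RNG state
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- dist2_to_centers(x, x[idx[1L], , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # all remaining points coincide with a chosen centre
      cand <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- if (length(cand)) cand[sample.int(length(cand), 1L)]
                else sample.int(n, 1L)
    } else {
      u <- stats::runif(1L) * sum(d2)
      idx[j] <- findInterval(u, cumsum(d2), rightmost.closed = TRUE) + 1L
      idx[j] <- min(idx[j], n)
    }
    d2 <- pmin(d2, dist2_to_centers(x, x[idx[j], , drop = FALSE])[, 1L])
  }
  x[idx, , drop = FALSE]
}

# Lloyd's algorithm; ties broken toward the lowest-index centre; an emptied
# cluster is reseeded at the point farthest from its centre
lloyd <- function(x, centers, max_iter) {
  k <- nrow(centers)
  assign_prev <- rep.int(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      sel <- assign_cur == j
      if (!any(sel)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign_cur)])
        assign_cur[far] <- j
        sel <- assign_cur == j
      }
      centers[j, ] <- colMeans(x[sel, , drop = FALSE])
    }
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
  }
  d2 <- dist2_to_centers(x, centers)
  assign_cur <- max.col(-d2, ties.method = "first")
  list(assignment = assign_cur, centers = centers,
       tot_withinss = sum(d2[cbind(seq_len(nrow(x)), assign_cur)]),
       iter = it)
}

#' K-means clustering of a signal matrix
#'
#' Features are the concatenated per-condition rows. Lloyd's algorithm with
#' k-means++ initialization; `n_init` restarts keep the solution with the
#' lowest total within-cluster sum of squares. Fully deterministic given
#' `seed`.
#'
#' @param sm A [extract_signal_matrix()] result.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed (or `NULL` to consume the current RNG stream).
#' @param n_init Number of restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param row_normalize Per-row feature normalization before clustering:
#'   `"none"` (raw signal; the default for the bare operation), `"l2"`
#'   (divide each row by its Euclidean norm, so clustering responds to the
#'   signal pattern rather than to domain length or amplitude), or `"sd"`
#'   (centre and scale each row). The pipeline driver uses `"l2"`; see the
#'   methods vignette.
#' @return List with `assignment` (integer cluster per region, named by
#'   region id), `centers`, `tot_withinss`, `k`.
#' @export
kmeans_cluster <- function(sm, k, seed = NULL, n_init = 10, max_iter = 300,
                           row_normalize = c("none", "l2", "sd")) {
  if (isFALSE(row_normalize)) row_normalize <- "none"
  row_normalize <- match.arg(row_normalize)
  if (k < 2) stop("kmeans_cluster: k must be >= 2")
  x <- do.call(cbind, sm$mat)
  if (nrow(x) < k) stop("kmeans_cluster: fewer regions than clusters")
  if (row_normalize == "sd") {
    mu <- rowMeans(x)
    s <- apply(x, 1L, stats::sd)
    s[s == 0] <- 1
    x <- (x - mu) / s
  } else if (row_normalize == "l2") {
    nrm <- sqrt(rowSums(x^2))
    nrm[nrm == 0] <- 1
    x <- x / nrm
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(x, kmeanspp_init(x, k), max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  names(best$assignment) <- as.character(sm$region_id)
  best$k <- k
  best
}

#' Mean signal per cluster and condition
#'
#' @param sm A [extract_signal_matrix()] result.
#' @param assignment Integer cluster assignment from [kmeans_cluster()].
#' @return Matrix of cluster x condition mean signal.
#' @export
cluster_condition_means <- function(sm, assignment) {
  ks <- sort(unique(assignment))
  out <- sapply(sm$mat, function(m) {
    vapply(ks, function(kk) mean(m[assignment == kk, , drop = FALSE]),
           numeric(1))
  })
  out <- matrix(out, nrow = length(ks),
                dimnames = list(as.character(ks), sm$conditions))
  out
}

#' Label clusters as gain / loss / common between two conditions
#'
#' With pseudocount eps = 1 added to both means, a cluster is `gain` if
#' `(mB + eps) / (mA + eps) >= fold_threshold`, `loss` if the reciprocal
#' ratio reaches the threshold, and `common` otherwise. Labels refer to the
#' change from condition A to condition B.
#'
#' @param mean_a,mean_b Non-negative cluster mean signal in conditions A and
#'   B (vectors of equal length).
#' @param fold_threshold Fold-change threshold (> 1, default 1.5).
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return Character vector of labels in `{"gain", "loss", "common"}`.
#' @export
classify_clusters <- function(mean_a, mean_b, fold_threshold = 1.5,
                              pseudocount = 1) {
  if (fold_threshold <= 1) stop("classify_clusters: fold_threshold must be > 1")
  stopifnot(length(mean_a) == length(mean_b))
  ra <- (mean_b + pseudocount) / (mean_a + pseudocount)
  ifelse(ra >= fold_threshold, "gain",
         ifelse(1 / ra >= fold_threshold, "loss", "common"))
}
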