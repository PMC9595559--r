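# Cluster-quality feedback: centroids, silhouette coefficients (with seeded
# downsampling, since the exact computation is O(n^2) and real tables run to
# ~50,000 bins), and average inter-cluster Euclidean distances. Bins labelled
# -1 (unclustered) or -2 (erased) are excluded from all analytics.

#' Per-cluster, per-sample centroids
#'
#' Arithmetic mean RDR and BAF of each non-negative cluster's member bins in
#' each sample, with member counts. Centroids drive the merge and absorb
#' operations and the copy-state assignment.
#'
#' @param x a [bin_table()].
#' @return An object of class `centroid_table`: cluster IDs (ascending),
#'   member counts, and `k x m` matrices `rdr` and `baf`. Convert with
#'   [as.data.frame()].
#' @export
compute_centroids <- function(x) {
  validate_bin_table(x)
  keep <- x$cluster >= 0L
  if (!any(keep)) {
    warning("no non-negative cluster labels: empty centroid table")
    ids <- integer(0)
  } else {
    ids <- sort(unique(x$cluster[keep]))
  }
  k <- length(ids)
  m <- length(x$samples)
  rdr <- matrix(NA_real_, k, m)
  baf <- matrix(NA_real_, k, m)
  size <- integer(k)
  for (j in seq_len(k)) {
    members <- which(x$cluster == ids[j])
    size[j] <- length(members)
    rdr[j, ] <- colMeans(x$rdr[members, , drop = FALSE])
    baf[j, ] <- colMeans(x$baf[members, , drop = FALSE])
  }
  structure(list(cluster = ids, size = size, rdr = rdr, baf = baf,
                 samples = x$samples),
            class = "centroid_table")
}

#' @export
as.data.frame.centroid_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(cluster = x$cluster, size = x$size)
  for (p in seq_along(x$samples)) {
    df[[paste0("RDR.", x$samples[p])]] <- x$rdr[, p]
    df[[paste0("BAF.", x$samples[p])]] <- x$baf[, p]
  }
  df
}

#' @export
print.centroid_table <- function(x, ...) {
  cat(sprintf("centroid_table: %d clusters x %d sample%s\n",
              length(x$cluster), length(x$samples),
              if (length(x$samples) == 1) "" else "s"))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

# per-point silhouette widths s(i) = (b(i) - a(i)) / max(a(i), b(i)) with
# Euclidean distances; singletons get 0 by convention
silhouette_widths <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  dmat <- as.matrix(stats::dist(features))
  ids <- sort(unique(labels))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own)
    if (length(same) == 1L) {
      widths[i] <- 0  # singleton: cohesion undefined, conventionally 0
      next
    }
    a <- sum(dmat[i, same]) / (length(same) - 1)
    b <- min(vapply(setdiff(ids, own), function(j) {
      mean(dmat[i, labels == j])
    }, numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  widths
}

#' Approximate per-cluster silhouette coefficients by downsampling
#'
#' The silhouette value of a bin lies in `[-1, 1]`; high values indicate the
#' bin is well matched to its own cluster and poorly matched to others. The
#' silhouette coefficient of a cluster is the mean over its member bins.
#' Because the exact computation costs O(n^2), it is approximated on a
#' seeded uniform subsample (without replacement) of at most `sample_cap`
#' bins; with `sample_cap >= n` the result is exact. Bins labelled `-1`/`-2`
#' are excluded.
#'
#' @param features matrix from [build_feature_matrix()].
#' @param labels integer vector of cluster labels, one per row of `features`.
#' @param sample_cap maximum number of bins entering the computation
#'   (default 2000).
#' @param seed integer seed for the subsample.
#' @return named numeric vector: mean silhouette per non-negative cluster.
#'   Clusters with one subsampled member get 0 (with a warning); clusters
#'   missing from the subsample get `NA`.
#' @export
silhouette_by_cluster <- function(features, labels, sample_cap = 2000,
                                  seed = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (!is_count(sample_cap, min = 2)) {
    stop("'sample_cap' must be an integer >= 2", call. = FALSE)
  }
  eligible <- which(labels >= 0)
  ids <- sort(unique(labels[eligible]))
  if (length(ids) < 2) {
    stop("silhouette requires at least two non-negative clusters", call. = FALSE)
  }
  idx <- if (length(eligible) > sample_cap) {
    with_seed(seed, sort(sample(eligible, sample_cap)))
  } else {
    eligible
  }
  sub_labels <- labels[idx]
  widths <- silhouette_widths(features[idx, , drop = FALSE], sub_labels)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (j in ids) {
    members <- which(sub_labels == j)
    if (length(members) == 0L) {
      warning(sprintf("cluster %d has no subsampled members; silhouette is NA", j))
    } else if (length(members) == 1L) {
      warning(sprintf("cluster %d has a single subsampled member; silhouette set to 0", j))
      out[as.character(j)] <- 0
    } else {
      out[as.character(j)] <- mean(widths[members])
    }
  }
  out
}

#' Average Euclidean distance from one cluster to each other cluster
#'
#' For the target cluster, the mean Euclidean distance over all cross pairs
#' of bins with each other non-negative cluster (subsampled to `sample_cap`
#' bins per cluster, seeded). Clusters at distance near 0 from the target are
#' good candidates for merging. `method = "centroid"` instead reports the
#' distance between cluster centroids.
#'
#' @inheritParams silhouette_by_cluster
#' @param target_cluster the cluster from which distances are measured.
#' @param method `"points"` (mean over cross pairs, default) or `"centroid"`.
#' @return named numeric vector of distances to each other cluster.
#' @export
mean_intercluster_distance <- function(features, labels, target_cluster,
                                       sample_cap = 2000, seed = NULL,
                                       method = c("points", "centroid")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  ids <- sort(unique(labels[labels >= 0]))
  if (!target_cluster %in% ids) {
    stop(sprintf("unknown target cluster %s", target_cluster), call. = FALSE)
  }
  others <- setdiff(ids, target_cluster)
  pick <- function(members) {
    if (length(members) > sample_cap) sort(sample(members, sample_cap)) else members
  }
  with_seed(seed, {
    a_idx <- pick(which(labels == target_cluster))
    out <- vapply(others, function(j) {
      b_idx <- pick(which(labels == j))
      if (method == "centroid") {
        sqrt(sum((colMeans(features[a_idx, , drop = FALSE]) -
                    colMeans(features[b_idx, , drop = FALSE]))^2))
      } else {
        d2 <- sqdist_to_centers(features[a_idx, , drop = FALSE],
                                features[b_idx, , drop = FALSE])
        mean(sqrt(pmax(d2, 0)))
      }
    }, numeric(1))
  })
  stats::setNames(out, others)
}
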