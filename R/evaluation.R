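# Ground-truth clustering comparison metrics: adjusted Rand index, V-measure
# and the exact silhouette. The exact silhouette doubles as the oracle for
# the downsampled approximation in silhouette_by_cluster().

check_label_pair <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop(sprintf("label vectors must have equal length (%d vs %d)",
                 length(truth), length(pred)), call. = FALSE)
  }
  if (length(truth) < 2) stop("need at least two points", call. = FALSE)
}

#' Adjusted Rand index between two clusterings
#'
#' Chance-corrected pair-counting agreement,
#' `ARI = (Index - E[Index]) / (Max - E[Index])`, computed from the
#' contingency table of the two labelings. Equals 1 when the partitions are
#' identical, is 0 in expectation for random assignments, and is invariant
#' under relabeling of either argument. Labels are opaque identifiers.
#'
#' @param truth,pred equal-length label vectors over the same points.
#' @return a value in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth, pred) {
  check_label_pair(truth, pred)
  tab <- table(truth, pred)
  n <- length(truth)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial (all singletons/one cluster)
  (sum_ij - expected) / (maximum - expected)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' V-measure between two clusterings
#'
#' Harmonic mean of homogeneity `h = 1 - H(C|K)/H(C)` and completeness
#' `c = 1 - H(K|C)/H(K)` (weight `beta = 1`), where C is the ground-truth
#' labeling and K the inferred one. Ranges from 0 (poor clustering) to 1
#' (partitions identical up to label permutation); symmetric in its two
#' arguments when `beta = 1`. Zero-entropy conventions: if `H(C) = 0`
#' homogeneity is 1; if `H(K) = 0` completeness is 1.
#'
#' @inheritParams adjusted_rand_index
#' @param beta weight of homogeneity in the harmonic mean.
#' @return a value in `[0, 1]`.
#' @export
v_measure <- function(truth, pred, beta = 1) {
  check_label_pair(truth, pred)
  tab <- table(truth, pred)
  n <- length(truth)
  h_c <- entropy_counts(rowSums(tab))
  h_k <- entropy_counts(colSums(tab))
  # conditional entropies from the joint
  h_c_given_k <- sum(apply(tab, 2, function(col) {
    if (sum(col) == 0) 0 else sum(col) / n * entropy_counts(col)
  }))
  h_k_given_c <- sum(apply(tab, 1, function(row) {
    if (sum(row) == 0) 0 else sum(row) / n * entropy_counts(row)
  }))
  homogeneity <- if (h_c == 0) 1 else 1 - h_c_given_k / h_c
  completeness <- if (h_k == 0) 1 else 1 - h_k_given_c / h_k
  if (homogeneity + completeness == 0) return(0)
  (1 + beta) * homogeneity * completeness / (beta * homogeneity + completeness)
}

#' Exact silhouette score
#'
#' Full O(n^2) silhouette computation over all points: per-point widths,
#' per-cluster means, and the overall mean. Serves as the oracle for the
#' downsampled [silhouette_by_cluster()].
#'
#' @param features numeric matrix, one row per point.
#' @param labels cluster labels, one per row; at least two distinct clusters.
#' @return list with `overall` (mean width), `by_cluster` (named vector of
#'   per-cluster means) and `widths` (per-point values in `[-1, 1]`).
#' @export
silhouette_exact <- function(features, labels) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  ids <- sort(unique(labels))
  if (length(ids) < 2) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  widths <- silhouette_widths(features, labels)
  by_cluster <- vapply(ids, function(j) mean(widths[labels == j]), numeric(1))
  list(overall = mean(widths),
       by_cluster = stats::setNames(by_cluster, ids),
       widths = widths)
}
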