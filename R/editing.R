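# Scripted cluster editing. Every operation changes only cluster labels —
# never coordinates, RDR or BAF — and appends an invertible entry to the
# table's operation log, so the final clustering can be replayed from the
# initial one and any operation undone.

new_log_entry <- function(op, params, bins, prev, new) {
  list(op = op, params = params, bins = as.integer(bins),
       prev = as.integer(prev), new = as.integer(new),
       time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

check_selection <- function(x, selection) {
  n <- nrow(x$bins)
  selection <- as.integer(selection)
  if (anyNA(selection) || anyDuplicated(selection) ||
      any(selection < 1L | selection > n)) {
    stop(sprintf("selection must be distinct bin indices in 1..%d", n),
         call. = FALSE)
  }
  selection
}

#' Assign selected bins to a cluster
#'
#' Sets the cluster label of exactly the selected bins, leaving all others
#' unchanged. Assigning `-1` marks bins unclustered; `-2` erases them (erased
#' bins are excluded from export and analytics).
#'
#' @param x a [bin_table()].
#' @param selection integer vector of bin indices (1-based, distinct).
#' @param cluster_id integer cluster ID, `>= -2`.
#' @return the updated table, with the operation appended to its edit log.
#' @export
assign_cluster <- function(x, selection, cluster_id) {
  validate_bin_table(x)
  if (length(cluster_id) != 1L || cluster_id < -2 || cluster_id != round(cluster_id)) {
    stop("'cluster_id' must be a single integer >= -2", call. = FALSE)
  }
  if (length(selection) == 0L) {
    warning("empty selection: nothing to assign")
    return(x)
  }
  selection <- check_selection(x, selection)
  prev <- x$cluster[selection]
  x$cluster[selection] <- as.integer(cluster_id)
  x$log <- c(x$log, list(new_log_entry("assign_cluster",
                                       list(cluster_id = as.integer(cluster_id)),
                                       selection, prev, x$cluster[selection])))
  x
}

#' Move selected bins into a fresh cluster
#'
#' Creates the next available cluster ID — the largest non-negative ID in use
#' plus one, or 0 when none is in use — and assigns the selection to it.
#' IDs are never recycled within a session, so an ID the user previously
#' emptied is not silently reused.
#'
#' @inheritParams assign_cluster
#' @return the updated table; the new cluster ID is attached as attribute
#'   `"new_id"`.
#' @export
new_cluster <- function(x, selection) {
  validate_bin_table(x)
  if (length(selection) == 0L) {
    stop("selection must be nonempty", call. = FALSE)
  }
  selection <- check_selection(x, selection)
  in_use <- x$cluster[x$cluster >= 0L]
  new_id <- if (length(in_use)) max(in_use) + 1L else 0L
  prev <- x$cluster[selection]
  x$cluster[selection] <- new_id
  x$log <- c(x$log, list(new_log_entry("new_cluster", list(cluster_id = new_id),
                                       selection, prev, x$cluster[selection])))
  attr(x, "new_id") <- new_id
  x
}

# flag pairs of centroid rows whose per-sample RDR and BAF gaps are all within
# the thresholds; returns the union-find component labels over the clusters
merge_components <- function(cent, t_rdr, t_baf) {
  kk <- length(cent$cluster)
  parent <- uf_new(kk)
  for (i in seq_len(kk - 1)) {
    for (j in (i + 1):kk) {
      ok <- all(abs(cent$rdr[i, ] - cent$rdr[j, ]) <= t_rdr) &&
        all(abs(cent$baf[i, ] - cent$baf[j, ]) <= t_baf)
      if (ok) parent <- uf_union(parent, i, j)
    }
  }
  uf_components(parent)
}

#' Merge clusters whose centroids are within per-sample thresholds
#'
#' Flags every pair of non-negative clusters whose centroids' RDR and BAF
#' values lie within the user-specified thresholds in every sample, then
#' aggregates flagged pairs into connected components (if 1-2 and 2-3 are
#' flagged, 1, 2 and 3 merge together even though 1-3 may not be flagged).
#' Within each component the largest cluster — most member bins, ties broken
#' toward the lowest ID — absorbs all others' bins. Reserved IDs `-1`/`-2`
#' never participate.
#'
#' @param x a [bin_table()] with at least two non-negative clusters.
#' @param t_rdr,t_baf non-negative per-sample thresholds (length 1 or m).
#' @param dry_run if `TRUE`, return the merge plan without modifying the table.
#' @return With `dry_run = TRUE`, the plan: a list of integer vectors, each a
#'   component of cluster IDs to be merged (components of size one are
#'   dropped). Otherwise the updated table with the plan attached as
#'   attribute `"merge_plan"`.
#' @export
merge_by_centroids <- function(x, t_rdr, t_baf, dry_run = FALSE) {
  validate_bin_table(x)
  m <- length(x$samples)
  t_rdr <- recycle_threshold(t_rdr, m, "t_rdr")
  t_baf <- recycle_threshold(t_baf, m, "t_baf")
  cent <- compute_centroids(x)
  if (length(cent$cluster) < 2) {
    stop("merging requires at least two non-negative clusters", call. = FALSE)
  }
  comp <- merge_components(cent, t_rdr, t_baf)
  plan <- lapply(split(cent$cluster, comp), as.integer)
  plan <- unname(plan[vapply(plan, length, integer(1)) > 1])
  if (dry_run) return(plan)
  for (ids in plan) {
    sizes <- cent$size[match(ids, cent$cluster)]
    # largest cluster keeps its label; ties break toward the lowest ID
    target <- ids[order(-sizes, ids)][1]
    sel <- which(x$cluster %in% setdiff(ids, target))
    prev <- x$cluster[sel]
    x$cluster[sel] <- target
    x$log <- c(x$log, list(new_log_entry(
      "merge_by_centroids",
      list(component = ids, target = target, t_rdr = t_rdr, t_baf = t_baf),
      sel, prev, x$cluster[sel])))
  }
  attr(x, "merge_plan") <- plan
  x
}

#' Absorb bins from donor clusters into recipient clusters
#'
#' For each bin in a "From" cluster, computes the Euclidean distance in the
#' joint 2m-dimensional feature space to its current cluster's centroid and
#' to every "To" cluster's centroid. The bin is reassigned only when the
#' nearest of those centroids belongs to a To cluster other than its own and
#' the bin-to-centroid RDR and BAF gaps are within the per-sample thresholds.
#' Centroids are frozen at entry — reassignments within one call never
#' cascade; iterate the call for repeated absorption. Bins outside the From
#' clusters are never touched.
#'
#' @param x a [bin_table()].
#' @param from_ids,to_ids non-negative cluster IDs currently in use.
#' @param t_rdr,t_baf non-negative per-sample thresholds (length 1 or m).
#' @return the updated table.
#' @export
absorb_bins <- function(x, from_ids, to_ids, t_rdr, t_baf) {
  validate_bin_table(x)
  m <- length(x$samples)
  t_rdr <- recycle_threshold(t_rdr, m, "t_rdr")
  t_baf <- recycle_threshold(t_baf, m, "t_baf")
  from_ids <- as.integer(from_ids)
  to_ids <- as.integer(to_ids)
  if (!length(from_ids) || !length(to_ids)) {
    stop("'from_ids' and 'to_ids' must be nonempty", call. = FALSE)
  }
  in_use <- unique(x$cluster[x$cluster >= 0L])
  if (any(from_ids < 0) || any(to_ids < 0) ||
      !all(c(from_ids, to_ids) %in% in_use)) {
    stop("'from_ids' and 'to_ids' must be non-negative cluster IDs in use",
         call. = FALSE)
  }
  cent <- compute_centroids(x)
  sel <- which(x$cluster %in% from_ids)
  prev <- x$cluster[sel]
  new <- prev
  for (s in seq_along(sel)) {
    i <- sel[s]
    current <- x$cluster[i]
    candidates <- sort(unique(c(to_ids, current)))
    ci <- match(candidates, cent$cluster)
    gaps_rdr <- abs(sweep(cent$rdr[ci, , drop = FALSE], 2, x$rdr[i, ]))
    gaps_baf <- abs(sweep(cent$baf[ci, , drop = FALSE], 2, x$baf[i, ]))
    d2 <- rowSums(gaps_rdr^2) + rowSums(gaps_baf^2)
    nearest <- candidates[which.min(d2)]  # ties toward the lower cluster ID
    ni <- which(candidates == nearest)
    if (nearest %in% to_ids && nearest != current &&
        all(gaps_rdr[ni, ] <= t_rdr) && all(gaps_baf[ni, ] <= t_baf)) {
      new[s] <- nearest
    }
  }
  changed <- which(new != prev)
  if (length(changed)) {
    x$cluster[sel[changed]] <- new[changed]
  }
  x$log <- c(x$log, list(new_log_entry(
    "absorb_bins",
    list(from = from_ids, to = to_ids, t_rdr = t_rdr, t_baf = t_baf),
    sel[changed], prev[changed], new[changed])))
  x
}

#' Undo the most recent editing operation
#'
#' Restores the labels recorded in the last log entry and removes the entry.
#'
#' @param x a [bin_table()] with a nonempty edit log.
#' @return the updated table.
#' @export
undo_edit <- function(x) {
  if (!length(x$log)) {
    warning("edit log is empty: nothing to undo")
    return(x)
  }
  entry <- x$log[[length(x$log)]]
  x$cluster[entry$bins] <- entry$prev
  x$log <- x$log[-length(x$log)]
  x
}

#' Retrieve the edit log of a bin table
#'
#' @param x a [bin_table()].
#' @return list of log entries (operation, parameters, affected bins,
#'   previous and new labels, timestamp).
#' @export
edit_log <- function(x) x$log

#' Replay an edit log over an initial clustering
#'
#' Applying the entries in order to the clustering the log started from
#' reproduces the final clustering.
#'
#' @param cluster integer vector of initial labels.
#' @param log an [edit_log()].
#' @return integer vector of final labels.
#' @export
replay_edit_log <- function(cluster, log) {
  cluster <- as.integer(cluster)
  for (entry in log) cluster[entry$bins] <- entry$new
  cluster
}

#' Write the edit log as a line-oriented text file
#'
#' One line per operation: name, parameters and the number of affected bins.
#'
#' @param x a [bin_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edit_log <- function(x, path) {
  lines <- vapply(x$log, function(e) {
    params <- paste(names(e$params),
                    vapply(e$params, function(p) paste(p, collapse = ","),
                           character(1)),
                    sep = "=", collapse = " ")
    sprintf("%s\t%s\tn_bins=%d", e$op, params, length(e$bins))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
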