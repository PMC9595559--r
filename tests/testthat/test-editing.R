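test_that("assigning a cluster changes exactly the selected bins", {
  tb <- line_table(c(1, 1, 2), cluster = c(1L, 1L, 2L))
  tb2 <- assign_cluster(tb, c(1, 2), 5L)
  expect_equal(tb2$cluster, c(5L, 5L, 2L))
  # coordinates and signals untouched
  expect_identical(tb2$bins, tb$bins)
  expect_identical(tb2$rdr, tb$rdr)
  # reserved IDs: erase and unassign
  erased <- assign_cluster(tb, 3, -2L)
  path <- tempfile(fileext = ".tsv")
  write_bin_table(erased, path)
  expect_equal(nrow(read_bin_table(path)$bins), 2)
  expect_equal(assign_cluster(tb, 1, -1L)$cluster[1], -1L)
  expect_warning(assign_cluster(tb, integer(0), 1L), "empty")
  expect_error(assign_cluster(tb, 1, -3L), ">= -2")
})

test_that("new clusters get the next available ID (max in use + 1)", {
  tb <- line_table(rep(1, 5), cluster = c(0L, 1L, 3L, 3L, -1L))
  tb2 <- new_cluster(tb, 5)
  expect_equal(attr(tb2, "new_id"), 4L)
  expect_equal(tb2$cluster[5], 4L)
  # base case: nothing in use
  tb3 <- new_cluster(line_table(rep(1, 3)), 1:2)
  expect_equal(attr(tb3, "new_id"), 0L)
  # consecutive calls give distinct, increasing IDs
  tb4 <- new_cluster(tb3, 3)
  expect_equal(attr(tb4, "new_id"), 1L)
  expect_error(new_cluster(tb, integer(0)), "nonempty")
})

# table with one bin per cluster-member at controlled centroid positions
centroid_fixture <- function() {
  # cluster 1: 10 bins at (1.00, 0.50); cluster 2: 40 at (1.02, 0.49);
  # cluster 3: 20 at (1.04, 0.48)
  rdr <- c(rep(1.00, 10), rep(1.02, 40), rep(1.04, 20))
  baf <- c(rep(0.50, 10), rep(0.49, 40), rep(0.48, 20))
  line_table(rdr, baf = baf, cluster = rep(c(1L, 2L, 3L), c(10, 40, 20)))
}

test_that("centroid merging chains flagged pairs into connected components", {
  tb <- centroid_fixture()
  # (1,2) and (2,3) within thresholds, (1,3) not: one chained component
  plan <- merge_by_centroids(tb, t_rdr = 0.03, t_baf = 0.02, dry_run = TRUE)
  expect_equal(plan, list(c(1L, 2L, 3L)))
  merged <- merge_by_centroids(tb, t_rdr = 0.03, t_baf = 0.02)
  # largest member (cluster 2, 40 bins) absorbs the others
  expect_equal(unique(merged$cluster), 2L)
  # zero thresholds with distinct centroids: empty plan, table unchanged
  expect_equal(merge_by_centroids(tb, 0, 0, dry_run = TRUE), list())
  same <- merge_by_centroids(tb, 0, 0)
  expect_equal(same$cluster, tb$cluster)
})

test_that("merge components match an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    cents <- cbind(runif(k, 0.5, 2.5), runif(k, 0, 0.5))
    sizes <- sample(2:6, k, replace = TRUE)
    rdr <- rep(cents[, 1], sizes)
    baf <- rep(cents[, 2], sizes)
    tb <- line_table(rdr, baf = baf, cluster = rep(seq_len(k), sizes))
    t_rdr <- runif(1, 0, 0.6)
    t_baf <- runif(1, 0, 0.25)
    plan <- merge_by_centroids(tb, t_rdr, t_baf, dry_run = TRUE)
    # oracle: build the flag graph explicitly, take its components
    adj <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      i != j && abs(cents[i, 1] - cents[j, 1]) <= t_rdr &&
        abs(cents[i, 2] - cents[j, 2]) <= t_baf
    }))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    oracle <- unname(Filter(function(v) length(v) > 1,
                            split(seq_len(k), comp)))
    oracle <- lapply(oracle, as.integer)
    normalize <- function(p) p[order(vapply(p, min, integer(1)))]
    expect_equal(normalize(plan), normalize(oracle))
  }
})

test_that("merge reduces cluster count by the planned component sizes", {
  tb <- centroid_fixture()
  before <- length(unique(tb$cluster[tb$cluster >= 0]))
  merged <- merge_by_centroids(tb, 0.03, 0.02)
  plan <- attr(merged, "merge_plan")
  after <- length(unique(merged$cluster[merged$cluster >= 0]))
  expect_equal(before - after, sum(vapply(plan, length, integer(1)) - 1L))
})

test_that("absorb reassigns only qualifying bins from donor clusters", {
  # bin 1 sits at (1.01, 0.49): nearest To centroid (1.0, 0.5), far From
  # centroid (2.0, 0.2) held up by bins 2-3
  tb <- line_table(c(1.01, 2.0, 2.0, 1.0, 1.0),
                   baf = c(0.49, 0.2, 0.2, 0.5, 0.5),
                   cluster = c(1L, 1L, 1L, 2L, 2L))
  moved <- absorb_bins(tb, from_ids = 1L, to_ids = 2L,
                       t_rdr = 0.05, t_baf = 0.05)
  expect_equal(moved$cluster, c(2L, 1L, 1L, 2L, 2L))
  # tight thresholds block the move
  blocked <- absorb_bins(tb, 1L, 2L, t_rdr = 0.001, t_baf = 0.001)
  expect_equal(blocked$cluster, tb$cluster)
  # a bin nearest its own centroid is ineligible
  stay <- line_table(c(2.0, 2.0, 1.0), baf = c(0.2, 0.2, 0.5),
                     cluster = c(1L, 1L, 2L))
  kept <- absorb_bins(stay, 1L, 2L, t_rdr = 5, t_baf = 5)
  expect_equal(kept$cluster[1:2], c(1L, 1L))
  # bins outside From clusters are never touched
  other <- absorb_bins(tb, 2L, 1L, t_rdr = 0, t_baf = 0)
  expect_equal(other$cluster[1:3], c(1L, 1L, 1L))
  expect_error(absorb_bins(tb, integer(0), 1L, 1, 1), "nonempty")
  expect_error(absorb_bins(tb, 1L, 99L, 1, 1), "in use")
})

test_that("absorb labels stay within the allowed set and do not cascade", {
  set.seed(9)
  rdr <- runif(40, 0.9, 2.1)
  tb <- line_table(rdr, baf = runif(40, 0.2, 0.5),
                   cluster = sample(0:3, 40, replace = TRUE))
  res <- absorb_bins(tb, from_ids = c(0L, 1L), to_ids = c(2L, 3L),
                     t_rdr = 1, t_baf = 1)
  expect_true(all(res$cluster %in% 0:3))
  outside <- which(!tb$cluster %in% c(0L, 1L))
  expect_equal(res$cluster[outside], tb$cluster[outside])
  moved <- which(res$cluster != tb$cluster)
  expect_true(all(res$cluster[moved] %in% c(2L, 3L)))
})

test_that("undo restores the previous labels exactly", {
  tb <- line_table(c(1, 1, 2), cluster = c(1L, 1L, 2L))
  tb2 <- assign_cluster(tb, 1:2, 5L)
  expect_equal(undo_edit(tb2)$cluster, tb$cluster)
  merged <- merge_by_centroids(centroid_fixture(), 0.03, 0.02)
  expect_equal(undo_edit(merged)$cluster, centroid_fixture()$cluster)
  two <- assign_cluster(assign_cluster(tb, 1, 7L), 3, 8L)
  expect_equal(undo_edit(undo_edit(two))$cluster, tb$cluster)
  expect_warning(undo_edit(tb), "empty")
})

test_that("replaying the edit log reproduces the final clustering", {
  set.seed(31)
  for (rep in 1:10) {
    tb <- line_table(runif(30, 0.8, 2.2), baf = runif(30, 0.1, 0.5),
                     cluster = sample(0:2, 30, replace = TRUE))
    initial <- tb$cluster
    for (op in 1:8) {
      choice <- sample(3, 1)
      if (choice == 1) {
        tb <- assign_cluster(tb, sample(30, sample(5, 1)), sample(0:5, 1))
      } else if (choice == 2) {
        tb <- new_cluster(tb, sample(30, sample(3, 1)))
      } else {
        ids <- unique(tb$cluster[tb$cluster >= 0])
        if (length(ids) >= 2) {
          from <- sample(ids, 1)
          to <- sample(setdiff(ids, from), 1)
          tb <- absorb_bins(tb, from, to, t_rdr = runif(1, 0, 1),
                            t_baf = runif(1, 0, 0.5))
        }
      }
    }
    expect_equal(replay_edit_log(initial, edit_log(tb)), tb$cluster)
  }
})

test_that("the edit log exports as a line-oriented text file", {
  tb <- assign_cluster(line_table(c(1, 2), cluster = c(0L, 1L)), 1, 1L)
  path <- tempfile(fileext = ".log")
  write_edit_log(tb, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^assign_cluster\t.*n_bins=1$")
})
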