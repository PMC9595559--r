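# Fixtures are built in code: small bin tables, TSV writers, and brute-force
# oracles kept independent of the implementation they check.

# a 2-sample, 3-bin table with assigned clusters
toy_table <- function(cluster = c(0L, 0L, 1L)) {
  bin_table(
    bins = data.frame(chrom = c("1", "1", "2"),
                      start = c(0L, 100L, 0L),
                      end = c(100L, 200L, 100L)),
    rdr = matrix(c(1.0, 1.2, 2.0,
                   0.9, 1.1, 2.1), ncol = 2),
    baf = matrix(c(0.5, 0.45, 0.2,
                   0.48, 0.44, 0.25), ncol = 2),
    samples = c("A", "B"),
    cluster = cluster
  )
}

# single-sample table with given per-bin features on one chromosome
line_table <- function(rdr, baf = rep(0.4, length(rdr)), cluster = NULL,
                       chrom = rep("1", length(rdr))) {
  n <- length(rdr)
  starts <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    starts[idx] <- (seq_along(idx) - 1L) * 100L
  }
  bin_table(
    bins = data.frame(chrom = chrom, start = starts, end = starts + 100L),
    rdr = matrix(rdr, ncol = 1),
    baf = matrix(baf, ncol = 1),
    samples = "S1",
    cluster = cluster
  )
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# the standard 2-sample 3-bin file, one row per bin per sample
toy_tsv <- function(with_cluster = TRUE, with_sample = TRUE) {
  header <- c("CHR", "START", "END", "RD", "BAF")
  if (with_cluster) header <- c(header, "CLUSTER")
  if (with_sample) header <- c(header, "SAMPLE")
  rows <- list(
    c("1", "0", "100", "1.0", "0.5", "0", "A"),
    c("1", "0", "100", "0.9", "0.48", "0", "B"),
    c("1", "100", "200", "1.2", "0.45", "0", "A"),
    c("1", "100", "200", "1.1", "0.44", "0", "B"),
    c("2", "0", "100", "2.0", "0.2", "1", "A"),
    c("2", "0", "100", "2.1", "0.25", "1", "B")
  )
  keep <- c(1:5, if (with_cluster) 6, if (with_sample) 7)
  write_tsv_text(c(paste(header, collapse = "\t"),
                   vapply(rows, function(r) paste(r[keep], collapse = "\t"),
                          character(1))))
}

# brute-force Rand-index oracle: enumerate all point pairs
ari_bruteforce <- function(truth, pred) {
  n <- length(truth)
  same_t <- outer(truth, truth, "==")[upper.tri(diag(n))]
  same_p <- outer(pred, pred, "==")[upper.tri(diag(n))]
  a <- sum(same_t & same_p)
  b <- sum(!same_t & !same_p)
  n11 <- sum(same_t)
  n01 <- sum(same_p)
  total <- choose(n, 2)
  expected <- n11 * n01 / total
  maximum <- (n11 + n01) / 2
  if (maximum == expected) return(1)
  (a - expected) / (maximum - expected)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_id) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return()
    }
    for (j in seq_len(next_id)) {
      recurse(c(labels, j), max(next_id, j + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# brute-force mean silhouette widths from explicit pairwise distances
silhouette_bruteforce <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  d <- as.matrix(dist(features))
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(j) mean(d[i, labels == j]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
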