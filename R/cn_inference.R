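# Integer allele-specific copy-state inference under the normal-contamination
# mixture model. A sample with tumor purity mu is a mixture of tumor cells
# carrying copy state (a, b) (a major, b minor copies, a >= b) and normal
# diploid (1, 1) cells. The expected signals follow:
#   E[BAF] = (mu * b + (1 - mu)) / (mu * (a + b) + 2 * (1 - mu))
#   E[RDR] = (mu * (a + b) + 2 * (1 - mu)) / (mu * rho + 2 * (1 - mu))
# where rho is the tumor ploidy. These closed forms reproduce the canonical
# anchors: BAF 1/3 for a (2, 1) gain in a pure sample, 0 for (3, 0), and 0.5
# for any balanced state or a pure-normal sample.

check_state <- function(a, b) {
  if (any(a != round(a)) || any(b != round(b)) || any(b < 0) || any(a < b)) {
    stop("copy state requires integers a >= b >= 0", call. = FALSE)
  }
}

#' Expected B-allele frequency of a copy state
#'
#' @param a,b integer major/minor allele copy numbers, `a >= b >= 0`.
#' @param mu tumor purity in `[0, 1]`.
#' @return expected BAF in `[0, 0.5]`; 0.5 whenever `a == b` or `mu == 0`.
#'   The combination `a = b = 0` with `mu = 1` (no DNA present) is undefined
#'   and raises an error.
#' @export
expected_baf <- function(a, b, mu) {
  check_state(a, b)
  if (any(mu < 0 | mu > 1)) stop("'mu' must lie in [0, 1]", call. = FALSE)
  denom <- mu * (a + b) + 2 * (1 - mu)
  if (any(denom == 0)) {
    stop("expected BAF is undefined for state (0, 0) at purity 1: no DNA",
         call. = FALSE)
  }
  (mu * b + (1 - mu)) / denom
}

#' Expected read-depth ratio of a copy state
#'
#' @inheritParams expected_baf
#' @param ploidy tumor ploidy `rho > 0` (average copies per position in tumor
#'   cells), the RDR normalizer.
#' @return non-negative expected RDR; 1 for state `(1, 1)` at `ploidy = 2`,
#'   increasing in total copies `a + b` at fixed purity and ploidy.
#' @export
expected_rdr <- function(a, b, mu, ploidy) {
  check_state(a, b)
  if (any(mu < 0 | mu > 1)) stop("'mu' must lie in [0, 1]", call. = FALSE)
  if (any(ploidy <= 0)) stop("'ploidy' must be positive", call. = FALSE)
  (mu * (a + b) + 2 * (1 - mu)) / (mu * ploidy + 2 * (1 - mu))
}

# candidate state grid, ordered so that the first argmin under strict "<"
# realises the tie rule: smaller total first, then larger b
enumerate_states <- function(max_total) {
  stopifnot(is_count(max_total))
  grid <- expand.grid(b = 0:max_total, a = 0:max_total)
  grid <- grid[grid$a >= grid$b & grid$a + grid$b <= max_total, c("a", "b")]
  grid[order(grid$a + grid$b, -grid$b), ]
}

# per-cluster squared residual between observed centroids and a state's
# expectations, summed over the given samples
state_residuals <- function(cent, states, purity, ploidy, samples) {
  k <- length(cent$cluster)
  res <- matrix(0, k, nrow(states))
  drop_state <- rep(FALSE, nrow(states))
  for (s in seq_len(nrow(states))) {
    a <- states$a[s]; b <- states$b[s]
    for (p in samples) {
      if (a == 0 && b == 0 && purity[p] == 1) {
        drop_state[s] <- TRUE
        break
      }
      e_rdr <- expected_rdr(a, b, purity[p], ploidy[p])
      e_baf <- expected_baf(a, b, purity[p])
      res[, s] <- res[, s] + (cent$rdr[, p] - e_rdr)^2 + (cent$baf[, p] - e_baf)^2
    }
  }
  res[, drop_state] <- Inf
  res
}

#' Assign integer copy states to cluster centroids
#'
#' For each cluster, finds the allele-specific copy state `(a, b)` with
#' `a >= b >= 0` and `a + b <= max_total` whose expected RDR and BAF under the
#' per-sample purity/ploidy compositions are closest (summed squared gaps over
#' samples) to the cluster's centroid. Ties break toward the smaller total
#' copy number, then the larger minor-allele count.
#'
#' @param centroids a [compute_centroids()] table.
#' @param purity per-sample tumor purity in `[0, 1]` (length 1 or m).
#' @param ploidy per-sample tumor ploidy `> 0` (length 1 or m).
#' @param max_total maximum total copy number `a + b` considered.
#' @return data.frame with columns `cluster`, `a`, `b`, `total`, `residual`.
#' @export
assign_states <- function(centroids, purity, ploidy, max_total = 6) {
  stopifnot(inherits(centroids, "centroid_table"))
  if (!length(centroids$cluster)) {
    stop("empty centroid table", call. = FALSE)
  }
  m <- length(centroids$samples)
  if (length(purity) == 1L) purity <- rep(purity, m)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, m)
  stopifnot(length(purity) == m, length(ploidy) == m)
  states <- enumerate_states(max_total)
  res <- state_residuals(centroids, states, purity, ploidy, seq_len(m))
  best <- apply(res, 1, which.min)  # first minimum: tie rule via grid order
  data.frame(cluster = centroids$cluster,
             a = states$a[best], b = states$b[best],
             total = states$a[best] + states$b[best],
             residual = res[cbind(seq_along(best), best)])
}

#' Grid scan of tumor purity and ploidy
#'
#' Scores each `(mu, rho)` grid point, per sample, by the member-count
#' weighted sum over clusters of the minimized copy-state residual from
#' [assign_states()] restricted to that sample, and ranks grid points by
#' ascending score. A flat zero score across several purities (all clusters
#' diploid `(1, 1)`) means purity is unidentifiable; such samples are flagged
#' in the `degenerate` attribute.
#'
#' @param centroids a [compute_centroids()] table.
#' @param mu_grid,rho_grid nonempty numeric grids of candidate purities and
#'   ploidies.
#' @param max_total maximum total copy number considered.
#' @return data.frame with columns `sample`, `mu`, `rho`, `score`, sorted by
#'   ascending score within sample; attribute `"degenerate"` is a named
#'   logical, one entry per sample.
#' @export
scan_purity_ploidy <- function(centroids, mu_grid, rho_grid, max_total = 6) {
  stopifnot(inherits(centroids, "centroid_table"),
            length(mu_grid) > 0, length(rho_grid) > 0)
  states <- enumerate_states(max_total)
  m <- length(centroids$samples)
  out <- vector("list", m)
  degenerate <- stats::setNames(logical(m), centroids$samples)
  for (p in seq_len(m)) {
    grid <- expand.grid(mu = mu_grid, rho = rho_grid)
    grid$score <- vapply(seq_len(nrow(grid)), function(g) {
      res <- state_residuals(centroids, states,
                             purity = rep(grid$mu[g], m),
                             ploidy = rep(grid$rho[g], m),
                             samples = p)
      sum(centroids$size * apply(res, 1, min))
    }, numeric(1))
    best <- min(grid$score)
    degenerate[p] <- sum(grid$score <= best + 1e-12) > 1 && best < 1e-12
    grid <- grid[order(grid$score), ]
    grid <- cbind(sample = centroids$samples[p], grid)
    rownames(grid) <- NULL
    out[[p]] <- grid
  }
  structure(do.call(rbind, out), degenerate = degenerate)
}

#' Classify a driver gene from the copy states covering it
#'
#' Collects the copy states of the clusters covering the gene's bins and
#' classifies the gene by total copy number against the diploid baseline:
#' total `> 2` amplified, `< 2` deleted, `= 2` unaffected (so copy-neutral
#' LOH `(2, 0)` counts as unaffected). When bins disagree, the majority by
#' bin count wins; ties give `"ambiguous"`. A gene overlapping no bins (or
#' only unclustered/stateless bins) is `"no-data"`, with a warning.
#'
#' @param gene a single-row data.frame (or list) with `symbol`, `chrom`,
#'   `start`, `end` — one row of [read_driver_genes()].
#' @param x a [bin_table()].
#' @param states per-cluster states from [assign_states()].
#' @return one of `"unaffected"`, `"deleted"`, `"amplified"`, `"ambiguous"`,
#'   `"no-data"`.
#' @export
classify_gene <- function(gene, x, states) {
  idx <- bins_overlapping(x, gene$chrom, gene$start, gene$end)
  if (!length(idx)) {
    warning(sprintf("gene '%s' overlaps no bins", gene$symbol))
    return("no-data")
  }
  cl <- x$cluster[idx]
  totals <- states$total[match(cl, states$cluster)]
  totals <- totals[!is.na(totals)]
  if (!length(totals)) {
    warning(sprintf("gene '%s' covered only by bins without a copy state",
                    gene$symbol))
    return("no-data")
  }
  verdicts <- ifelse(totals > 2, "amplified", ifelse(totals < 2, "deleted", "unaffected"))
  counts <- table(verdicts)
  top <- counts[counts == max(counts)]
  if (length(top) > 1) return("ambiguous")
  names(top)
}

#' Classify every driver gene in an annotation table
#'
#' @param genes data.frame from [read_driver_genes()].
#' @param x a [bin_table()].
#' @param states per-cluster states from [assign_states()].
#' @return data.frame with columns `symbol` and `class`.
#' @export
classify_genes <- function(genes, x, states) {
  cls <- vapply(seq_len(nrow(genes)), function(i) {
    classify_gene(genes[i, , drop = FALSE], x, states)
  }, character(1))
  data.frame(symbol = genes$symbol, class = cls, stringsAsFactors = FALSE)
}
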