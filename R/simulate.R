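# Synthetic multi-sample tumor sequencing generator. Emulates the structure
# of multi-clone bulk DNA-seq simulations: a genome of fixed-width bins is
# partitioned into contiguous segments, each tumor clone carries an integer
# allele-specific copy state per segment, and each sample is a mixture of
# tumor clones and normal diploid cells at a planted purity. Observed RDR is
# the closed-form mixture expectation plus truncated Gaussian noise; observed
# BAF is binomial given a simulated SNP-read coverage, mirrored into
# [0, 0.5]. The ground-truth cluster of a bin is the tuple of clone states at
# its segment, so segments with identical states across clones share a label
# (the premise of global segmentation: recurrent CNAs cluster genome-wide).

#' Simulation configuration
#'
#' Defaults describe a desk-scale instance: 2 chromosomes of 250 bins of
#' 50 kb, two samples, two tumor clones, 20 planted segments of which 60%
#' are shared across clones, per-sample purities 0.6 and 0.8, RDR noise
#' sd 0.05 and 500 simulated SNP reads per bin — separable but nontrivial.
#'
#' Clone proportions default to a deterministic per-sample split of the
#' purity (cyclic weights), so that clone mixtures differ between samples and
#' clone-specific segments remain distinguishable.
#'
#' @param seed integer seed driving all randomness.
#' @param n_chrom,bins_per_chrom,bin_width genome layout (bins are fixed width,
#'   in bp).
#' @param samples sample names (length m).
#' @param n_clones number of tumor clones (>= 1).
#' @param n_segments number of planted contiguous segments across the genome.
#' @param max_total maximum planted total copy number `a + b`.
#' @param fraction_shared fraction of segments whose state is shared by all
#'   clones.
#' @param purity per-sample tumor purity in `[0, 1]` (length m).
#' @param clone_props optional `n_clones x m` matrix of per-sample clone
#'   proportions; column p must sum to `purity[p]`.
#' @param rdr_noise_sd Gaussian noise sd added to expected RDR (truncated at 0).
#' @param baf_coverage simulated SNP-read count per bin for binomial BAF
#'   noise; `Inf` yields exact expectations.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chrom = 2, bins_per_chrom = 250,
                              bin_width = 50000, samples = c("S1", "S2"),
                              n_clones = 2, n_segments = 20, max_total = 6,
                              fraction_shared = 0.6, purity = c(0.6, 0.8),
                              clone_props = NULL, rdr_noise_sd = 0.05,
                              baf_coverage = 500) {
  m <- length(samples)
  stopifnot(is_count(seed, min = 0), is_count(n_chrom), is_count(bins_per_chrom),
            is_count(bin_width), is_count(n_clones), is_count(n_segments),
            is_count(max_total), m >= 1,
            is_prob(fraction_shared), length(purity) == m,
            all(purity >= 0 & purity <= 1),
            rdr_noise_sd >= 0, baf_coverage >= 1)
  total_bins <- n_chrom * bins_per_chrom
  if (n_segments > total_bins) {
    stop("n_segments must not exceed the total number of bins", call. = FALSE)
  }
  if (is.null(clone_props)) {
    # cyclic weights: clone c in sample p gets purity[p] * w, w a shifted ramp
    clone_props <- matrix(0, n_clones, m)
    for (p in seq_len(m)) {
      w <- (seq_len(n_clones) + (p - 1) - 1) %% n_clones + 1
      clone_props[, p] <- purity[p] * w / sum(w)
    }
  }
  clone_props <- as.matrix(clone_props)
  if (nrow(clone_props) != n_clones || ncol(clone_props) != m ||
      any(clone_props < 0) ||
      any(abs(colSums(clone_props) - purity) > 1e-9)) {
    stop("clone_props must be n_clones x m, non-negative, with columns summing to purity",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_chrom = n_chrom,
                 bins_per_chrom = bins_per_chrom, bin_width = bin_width,
                 samples = samples, n_clones = n_clones,
                 n_segments = n_segments, max_total = max_total,
                 fraction_shared = fraction_shared, purity = purity,
                 clone_props = clone_props, rdr_noise_sd = rdr_noise_sd,
                 baf_coverage = baf_coverage),
            class = "simulation_config")
}

#' Plant clone copy-number profiles over contiguous segments
#'
#' Partitions the bin-index space into `n_segments` contiguous segments at
#' seeded random breakpoints and draws an allele-specific copy state
#' (`a >= b >= 0`, `1 <= a + b <= max_total`; whole-segment homozygous
#' deletions are excluded) per clone per segment. A seeded fraction of
#' segments is shared — all clones carry the same state there; the rest are
#' clone-specific. The normal clone is implicitly `(1, 1)` everywhere.
#'
#' @param config a [simulation_config()].
#' @return list of class `clone_profiles`: `segment_of_bin` (length n),
#'   `segments` (data.frame with first/last bin index), state matrices `a`
#'   and `b` (`n_clones x n_segments`), `truth_of_segment` (ground-truth
#'   cluster ID per segment: identical clone-state tuples share an ID), and
#'   the config.
#' @export
plant_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_chrom * config$bins_per_chrom
  k <- config$n_segments
  with_seed(config$seed, {
    breaks <- if (k > 1) sort(sample(2:n, k - 1)) else integer(0)
    seg_start <- c(1L, breaks)
    seg_end <- c(breaks - 1L, n)
    segment_of_bin <- rep(seq_len(k), seg_end - seg_start + 1L)

    # candidate states: a >= b >= 0, 1 <= a + b <= max_total
    grid <- enumerate_states(config$max_total)
    grid <- grid[grid$a + grid$b >= 1, ]
    n_shared <- round(config$fraction_shared * k)
    shared <- sort(sample(seq_len(k), n_shared))
    a <- matrix(0L, config$n_clones, k)
    b <- matrix(0L, config$n_clones, k)
    for (s in seq_len(k)) {
      if (s %in% shared) {
        pick <- sample(nrow(grid), 1)
        a[, s] <- grid$a[pick]
        b[, s] <- grid$b[pick]
      } else {
        pick <- sample(nrow(grid), config$n_clones, replace = TRUE)
        a[, s] <- grid$a[pick]
        b[, s] <- grid$b[pick]
      }
    }
  })
  tuple <- apply(rbind(a, b), 2, paste, collapse = ",")
  truth_of_segment <- as.integer(factor(tuple, levels = unique(tuple))) - 1L
  structure(list(segment_of_bin = segment_of_bin,
                 segments = data.frame(segment = seq_len(k),
                                       first_bin = seg_start, last_bin = seg_end),
                 a = a, b = b,
                 truth_of_segment = truth_of_segment,
                 config = config),
            class = "clone_profiles")
}

# closed-form mixture expectations per bin and sample, normal clone at (1, 1)
# with ploidy 2; clone ploidies are the per-clone mean total copies over bins
# (bins share a width, so the mean is length-weighted by construction)
mixture_expectations <- function(profiles) {
  config <- profiles$config
  seg <- profiles$segment_of_bin
  n <- length(seg)
  m <- length(config$samples)
  totals <- profiles$a + profiles$b            # n_clones x n_segments
  minors <- profiles$b
  clone_ploidy <- rowMeans(totals[, seg, drop = FALSE])
  e_rdr <- matrix(NA_real_, n, m)
  e_baf <- matrix(NA_real_, n, m)
  for (p in seq_len(m)) {
    u <- config$clone_props[, p]
    u_normal <- 1 - config$purity[p]
    num_total <- u_normal * 2 + colSums(u * totals[, seg, drop = FALSE])
    num_minor <- u_normal * 1 + colSums(u * minors[, seg, drop = FALSE])
    denom <- u_normal * 2 + sum(u * clone_ploidy)
    e_rdr[, p] <- num_total / denom
    e_baf[, p] <- num_minor / num_total
  }
  list(rdr = e_rdr, baf = pmin(e_baf, 1 - e_baf))
}

#' Emit noisy observations from planted profiles
#'
#' Computes the closed-form expected RDR and BAF of every bin in every sample
#' under the clone mixture, then adds noise: RDR gets Gaussian noise
#' (sd `rdr_noise_sd`, truncated at 0); BAF is drawn as
#' `Binomial(baf_coverage, E[BAF]) / baf_coverage` and mirrored to `<= 0.5`
#' (`baf_coverage = Inf` gives the exact expectation). With
#' `rdr_noise_sd = 0` and infinite coverage the emissions equal the
#' expectations exactly.
#'
#' @param profiles a [plant_profiles()] result.
#' @return list with `table` (a [bin_table()], all bins unclustered), `truth`
#'   (integer ground-truth label per bin), `expected` (noise-free RDR/BAF
#'   matrices) and `profiles`.
#' @export
emit_observations <- function(profiles) {
  stopifnot(inherits(profiles, "clone_profiles"))
  config <- profiles$config
  n <- length(profiles$segment_of_bin)
  m <- length(config$samples)
  ex <- mixture_expectations(profiles)
  with_seed(config$seed + 1L, {
    rdr <- pmax(ex$rdr + matrix(stats::rnorm(n * m, sd = config$rdr_noise_sd), n, m), 0)
    baf <- if (is.finite(config$baf_coverage)) {
      cov <- config$baf_coverage
      matrix(stats::rbinom(n * m, cov, as.vector(ex$baf)) / cov, n, m)
    } else {
      ex$baf
    }
  })
  baf <- pmin(baf, 1 - baf)
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), each = config$bins_per_chrom)
  offset <- (seq_len(n) - 1L) %% config$bins_per_chrom
  bins <- data.frame(chrom = chrom,
                     start = offset * config$bin_width,
                     end = (offset + 1L) * config$bin_width)
  truth <- profiles$truth_of_segment[profiles$segment_of_bin]
  list(table = bin_table(bins, rdr, baf, samples = config$samples),
       truth = truth, expected = ex, profiles = profiles)
}

#' Simulate a bin table with known ground truth
#'
#' Convenience composition of [plant_profiles()] and [emit_observations()].
#'
#' @param config a [simulation_config()].
#' @return see [emit_observations()].
#' @export
simulate_bins <- function(config) {
  emit_observations(plant_profiles(config))
}

#' Write a simulated dataset to files
#'
#' Writes `bins.tsv` (the bin dialect, `CLUSTER = -1` throughout) and
#' `truth.tsv` (per-bin ground-truth label plus the clone copy states) into
#' `out_dir`. Rereading `bins.tsv` with [read_bin_table()] passes all
#' validations; the same seed yields byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir writable output directory (created if needed).
#' @return named character vector with the two file paths, invisibly; the
#'   simulated object is attached as attribute `"simulation"`.
#' @export
simulate_to_files <- function(config, out_dir) {
  sim <- simulate_bins(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bins_path <- file.path(out_dir, "bins.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_bin_table(sim$table, bins_path)
  prof <- sim$profiles
  seg <- prof$segment_of_bin
  truth_df <- data.frame(
    CHR = sim$table$bins$chrom,
    START = sim$table$bins$start,
    END = sim$table$bins$end,
    LABEL = sim$truth,
    SEGMENT = seg
  )
  for (c in seq_len(config$n_clones)) {
    truth_df[[sprintf("CLONE%d_A", c)]] <- prof$a[c, seg]
    truth_df[[sprintf("CLONE%d_B", c)]] <- prof$b[c, seg]
  }
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(structure(c(bins = bins_path, truth = truth_path),
                      simulation = sim))
}
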