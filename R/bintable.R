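#' Bin table: multi-sample RDR/BAF values over genomic bins
#'
#' A `bin_table` holds `n` genomic bins observed in `m` samples: per-bin,
#' per-sample read-depth ratios (RDR) and B-allele frequencies (BAF), genomic
#' coordinates, and one integer cluster label per bin. Cluster IDs `-1`
#' (unclustered) and `-2` (erased) are reserved; erased bins are dropped on
#' export. Coordinates are 0-based with inclusive start and exclusive end;
#' they are used only for ordering, adjacency and gene overlap.
#'
#' @param bins data.frame with columns `chrom` (character), `start`, `end`
#'   (non-negative integers, `end > start`); bins of one chromosome must be
#'   contiguous in the row order and sorted by `start`.
#' @param rdr,baf numeric `n x m` matrices; RDR must be non-negative, BAF in
#'   `[0, 1]` (values above 0.5 are mirrored to `1 - BAF`).
#' @param samples character vector of `m` sample names.
#' @param cluster integer vector of length `n` with entries `>= -2`; defaults
#'   to `-1` (unclustered) for every bin.
#' @param extra optional data.frame of pass-through columns with `n * m` rows
#'   in bin-major order (all samples of bin 1, then bin 2, ...), re-emitted
#'   unchanged on export.
#' @return An object of class `bin_table`.
#' @seealso [read_bin_table()], [write_bin_table()], [segments_from_clustering()]
#' @export
bin_table <- function(bins, rdr, baf, samples = NULL, cluster = NULL, extra = NULL) {
  rdr <- as.matrix(rdr)
  baf <- as.matrix(baf)
  n <- nrow(bins)
  m <- ncol(rdr)
  if (is.null(samples)) samples <- paste0("S", seq_len(m))
  if (is.null(cluster)) cluster <- rep(-1L, n)
  # mirror BAF into [0, 0.5]: the allelic-imbalance view presumes BAF <= 0.5
  baf[] <- pmin(baf, 1 - baf)
  x <- structure(
    list(
      bins = data.frame(chrom = as.character(bins$chrom),
                        start = as.integer(bins$start),
                        end = as.integer(bins$end),
                        stringsAsFactors = FALSE),
      samples = as.character(samples),
      rdr = unname(rdr),
      baf = unname(baf),
      cluster = as.integer(cluster),
      extra = extra,
      log = list()
    ),
    class = "bin_table"
  )
  validate_bin_table(x)
  x
}

#' Validate a bin table's structural invariants
#'
#' Checks the ordering rules of the input dialect — (1) bins of one chromosome
#' are grouped and sorted by position, (2) per-position rows are grouped,
#' (3) every bin is present in every sample — plus coordinate sanity, value
#' ranges (RDR `>= 0`, BAF in `[0, 0.5]`) and reserved cluster IDs.
#'
#' @param x a `bin_table`.
#' @return `x`, invisibly; errors describe the violated rule.
#' @export
validate_bin_table <- function(x) {
  stopifnot(inherits(x, "bin_table"))
  n <- nrow(x$bins)
  m <- length(x$samples)
  if (!is.matrix(x$rdr) || !is.matrix(x$baf) ||
      nrow(x$rdr) != n || nrow(x$baf) != n ||
      ncol(x$rdr) != m || ncol(x$baf) != m) {
    stop("rule (3) violated: RDR/BAF must be fully populated n x m matrices",
         call. = FALSE)
  }
  if (anyNA(x$rdr) || anyNA(x$baf)) {
    stop("rule (3) violated: missing RDR/BAF values are not allowed", call. = FALSE)
  }
  if (anyDuplicated(x$samples)) stop("duplicate sample names", call. = FALSE)
  if (any(x$bins$start < 0)) stop("bin start positions must be >= 0", call. = FALSE)
  if (any(x$bins$end <= x$bins$start)) {
    stop("bin end must be greater than start", call. = FALSE)
  }
  key <- paste(x$bins$chrom, x$bins$start, x$bins$end)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate bin %s: the (chrom, start, end) triple must be unique",
                 key[anyDuplicated(key)]), call. = FALSE)
  }
  # rule (1): chromosome blocks contiguous, starts increasing within a block
  blocks <- rle(x$bins$chrom)$values
  if (anyDuplicated(blocks)) {
    stop(sprintf(
      "ordering rule (1) violated: rows of chromosome '%s' are not grouped together",
      blocks[anyDuplicated(blocks)]), call. = FALSE)
  }
  bad <- which(diff(x$bins$start) <= 0 & x$bins$chrom[-1] == x$bins$chrom[-n])
  if (n > 1 && length(bad)) {
    stop(sprintf(
      "ordering rule (1) violated: chromosome '%s' is not sorted by start at row %d",
      x$bins$chrom[bad[1] + 1], bad[1] + 1), call. = FALSE)
  }
  if (any(x$rdr < 0)) stop("RDR values must be >= 0", call. = FALSE)
  if (any(x$baf < 0 | x$baf > 0.5)) {
    stop("BAF values must lie in [0, 0.5] after mirroring", call. = FALSE)
  }
  if (length(x$cluster) != n || any(x$cluster < -2L)) {
    stop("cluster labels must be one per bin with values >= -2", call. = FALSE)
  }
  if (!is.null(x$extra) && nrow(x$extra) != n * m) {
    stop("extra columns must have one row per bin per sample", call. = FALSE)
  }
  invisible(x)
}

#' Read a bin TSV file
#'
#' Reads the tab-separated bin dialect: a header row with at least `CHR`,
#' `START`, `END`, `RD` and `BAF` (any column order), an optional `CLUSTER`
#' column and an optional `SAMPLE` column. Rows must obey three ordering
#' rules: (1) all bins of one chromosome grouped together and sorted by
#' position; (2) rows of the same genomic position but different samples
#' grouped together; (3) every bin present in every sample. When `CLUSTER`
#' is absent all bins are marked unclustered (`-1`). BAF values above 0.5
#' are mirrored to `1 - BAF`. Unrecognised columns are preserved and
#' re-emitted by [write_bin_table()].
#'
#' When no `SAMPLE` column is present and each position repeats over
#' consecutive rows, samples are assigned by within-position row order and
#' named `S1, ..., Sm`.
#'
#' @param path path to a tab-separated file.
#' @return A [bin_table()].
#' @export
read_bin_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = "NA")
  required <- c("CHR", "START", "END", "RD", "BAF")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column '%s'", missing_cols[1]), call. = FALSE)
  }
  for (col in c("RD", "BAF")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop(sprintf("column '%s' must be numeric with no missing values", col),
           call. = FALSE)
    }
  }
  for (col in c("START", "END")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]])) {
      stop(sprintf("column '%s' must be integer positions", col), call. = FALSE)
    }
  }
  df$CHR <- as.character(df$CHR)

  key <- paste(df$CHR, df$START, df$END)
  # rule (2): rows of the same position must be consecutive
  runs <- rle(key)
  if (anyDuplicated(runs$values)) {
    dup <- runs$values[anyDuplicated(runs$values)]
    stop(sprintf(
      "ordering rule (2) violated: rows for bin %s are not grouped together",
      dup), call. = FALSE)
  }
  n <- length(runs$values)
  pos_index <- rep(seq_len(n), runs$lengths)

  if ("SAMPLE" %in% names(df)) {
    samples <- unique(as.character(df$SAMPLE))
    m <- length(samples)
    sample_index <- match(as.character(df$SAMPLE), samples)
  } else {
    m <- runs$lengths[1]
    samples <- paste0("S", seq_len(m))
    sample_index <- unlist(lapply(runs$lengths, seq_len), use.names = FALSE)
  }
  # rule (3): every bin present in every sample, exactly once
  counts <- tabulate(pos_index, nbins = n)
  if (any(counts != m)) {
    bad <- which(counts != m)[1]
    stop(sprintf(
      "ordering rule (3) violated: bin %s has %d rows but there are %d samples",
      runs$values[bad], counts[bad], m), call. = FALSE)
  }
  if (anyDuplicated(cbind(pos_index, sample_index))) {
    stop("ordering rule (3) violated: a bin appears twice for the same sample",
         call. = FALSE)
  }

  first <- match(seq_len(n), pos_index)
  bins <- data.frame(chrom = df$CHR[first],
                     start = as.integer(df$START[first]),
                     end = as.integer(df$END[first]),
                     stringsAsFactors = FALSE)

  rdr <- matrix(NA_real_, n, m)
  baf <- matrix(NA_real_, n, m)
  idx <- cbind(pos_index, sample_index)
  rdr[idx] <- df$RD
  baf[idx] <- df$BAF
  if (any(df$BAF < 0 | df$BAF > 1)) {
    stop("column 'BAF' must lie in [0, 1]", call. = FALSE)
  }

  if ("CLUSTER" %in% names(df)) {
    if (!is.numeric(df$CLUSTER) || anyNA(df$CLUSTER)) {
      stop("column 'CLUSTER' must be integer with no missing values", call. = FALSE)
    }
    cl <- matrix(NA_integer_, n, m)
    cl[idx] <- as.integer(df$CLUSTER)
    if (any(apply(cl, 1, function(r) length(unique(r))) != 1)) {
      stop("CLUSTER must agree across samples of the same bin", call. = FALSE)
    }
    cluster <- cl[, 1]
  } else {
    cluster <- rep(-1L, n)
  }

  extra_names <- setdiff(names(df),
                         c("CHR", "START", "END", "RD", "BAF", "CLUSTER", "SAMPLE"))
  extra <- NULL
  if (length(extra_names)) {
    # reorder pass-through rows to canonical bin-major order
    ord <- order(pos_index, sample_index)
    extra <- df[ord, extra_names, drop = FALSE]
    rownames(extra) <- NULL
  }

  bin_table(bins, rdr, baf, samples = samples, cluster = cluster, extra = extra)
}

# shortest decimal representation that round-trips to the same double
format_roundtrip <- function(x) {
  out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  bad <- as.numeric(out) != x
  if (any(bad)) out[bad] <- sprintf("%.17g", x[bad])
  out
}

#' Write a bin table as TSV
#'
#' Emits the same dialect read by [read_bin_table()]: one row per bin per
#' sample, bins in table order, samples grouped within each position. Bins
#' with cluster `-2` (erased) are not exported. Pass-through columns are
#' re-emitted unchanged. A `SAMPLE` column is written whenever `m > 1`.
#'
#' @param x a `bin_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bin_table <- function(x, path) {
  validate_bin_table(x)
  df <- as.data.frame(x)
  keep <- df$CLUSTER != -2L
  df <- df[keep, , drop = FALSE]
  if (length(x$samples) == 1L) df$SAMPLE <- NULL
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- format_roundtrip(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @describeIn bin_table long-format view: one row per bin per sample with
#'   columns `CHR`, `START`, `END`, `SAMPLE`, `RD`, `BAF`, `CLUSTER` and any
#'   pass-through columns.
#' @param x,row.names,optional,... standard [as.data.frame()] arguments.
#' @export
as.data.frame.bin_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- nrow(x$bins)
  m <- length(x$samples)
  i <- rep(seq_len(n), each = m)
  p <- rep(seq_len(m), times = n)
  df <- data.frame(
    CHR = x$bins$chrom[i],
    START = x$bins$start[i],
    END = x$bins$end[i],
    SAMPLE = x$samples[p],
    RD = x$rdr[cbind(i, p)],
    BAF = x$baf[cbind(i, p)],
    CLUSTER = x$cluster[i],
    stringsAsFactors = FALSE
  )
  if (!is.null(x$extra)) df <- cbind(df, x$extra)
  df
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d bins x %d sample%s (%d chromosome%s)\n",
              nrow(x$bins), length(x$samples),
              if (length(x$samples) == 1) "" else "s",
              length(unique(x$bins$chrom)),
              if (length(unique(x$bins$chrom)) == 1) "" else "s"))
  cl <- x$cluster
  cat(sprintf("  clusters: %d assigned, %d unclustered (-1), %d erased (-2)\n",
              sum(cl >= 0), sum(cl == -1L), sum(cl == -2L)))
  invisible(x)
}

#' Read a driver-gene annotation file
#'
#' Parses a tab-separated file with columns `symbol` and `Genome Location`,
#' the latter formatted `{CHR}:{START}-{END}`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`.
#' @export
read_driver_genes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c("symbol", "Genome Location")) {
    if (!col %in% names(df)) {
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
    }
  }
  loc <- as.character(df[["Genome Location"]])
  m <- regmatches(loc, regexec("^(.+):([0-9]+)-([0-9]+)$", loc))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed 'Genome Location' at row %d: '%s'", bad[1], loc[bad[1]]),
         call. = FALSE)
  }
  genes <- data.frame(
    symbol = as.character(df$symbol),
    chrom = vapply(m, `[`, character(1), 2L),
    start = as.integer(vapply(m, `[`, character(1), 3L)),
    end = as.integer(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  if (any(genes$end <= genes$start)) {
    bad <- which(genes$end <= genes$start)[1]
    stop(sprintf("gene '%s' (row %d): end must be greater than start",
                 genes$symbol[bad], bad), call. = FALSE)
  }
  genes
}

#' Bins overlapping a genomic interval
#'
#' Half-open interval intersection (inclusive start, exclusive end) on one
#' chromosome; used to locate the bins spanned by a driver gene.
#'
#' @param x a `bin_table`.
#' @param chrom chromosome name.
#' @param start,end interval bounds, `start < end`.
#' @return integer vector of bin indices (possibly empty).
#' @export
bins_overlapping <- function(x, chrom, start, end) {
  stopifnot(inherits(x, "bin_table"), start < end)
  which(x$bins$chrom == as.character(chrom) & x$bins$start < end & x$bins$end > start)
}

#' Collapse a clustering into contiguous segments
#'
#' Maximal runs of consecutive bins with the same cluster label within one
#' chromosome, in table order. The segments partition the bins: their bin
#' counts sum to `n`.
#'
#' @param x a `bin_table`.
#' @return data.frame with columns `chrom`, `start`, `end`, `cluster`,
#'   `n_bins`; BED-like, one row per segment.
#' @export
segments_from_clustering <- function(x) {
  validate_bin_table(x)
  n <- nrow(x$bins)
  run_key <- paste(x$bins$chrom, x$cluster, sep = "\r")
  r <- rle(run_key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    chrom = x$bins$chrom[starts],
    start = x$bins$start[starts],
    end = x$bins$end[ends],
    cluster = x$cluster[starts],
    n_bins = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Write a segment table as BED-like TSV
#'
#' @param segments output of [segments_from_clustering()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- segments
  names(out) <- c("CHR", "START", "END", "CLUSTER", "N_BINS")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
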