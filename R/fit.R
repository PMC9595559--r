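#' Segment a bin table
#'
#' Central fitting function combining global and local segmentation of
#' multi-sample RDR/BAF bin data. Global segmentation fits a k-component
#' Gaussian mixture in the joint 2m-dimensional feature space
#' ([fit_global_gmm()]); local segmentation Viterbi-decodes a hidden Markov
#' model built on the fitted components ([local_decode_hmm()]). The hybrid
#' mode runs them sequentially: the mixture supplies the k composite
#' distributions that best describe the data, and the HMM then enforces
#' genomic contiguity, recovering segments while keeping recurrent
#' copy-number states in one cluster.
#'
#' @param x a [bin_table()].
#' @param mode `"hybrid"` (GMM then HMM, the default), `"global"` (GMM
#'   labels), or `"local"` (HMM decoding of a supplied mixture `model`).
#' @param k number of clusters; if `NULL`, chosen by BIC over `k_range`.
#' @param k_range candidate range for [select_k()] when `k` is `NULL`.
#' @param tau HMM self-transition probability; ignored for `mode = "global"`.
#' @param seed integer seed for the mixture fit.
#' @param model an existing `cna_gmm`, required for `mode = "local"` and
#'   otherwise fitted internally.
#' @param ... further arguments passed to [fit_global_gmm()].
#' @return An object of class `cna_fit`: the input table with updated cluster
#'   labels (`$table`), the fitted mixture (`$model`), the final 0-based
#'   `$clustering`, the run-collapsed `$segments`, and the call parameters.
#'   Methods: [print()], [summary()], [coef()] (component means), [fitted()]
#'   (labels), [plot()].
#' @examples
#' sim <- simulate_bins(simulation_config(seed = 1))
#' fit <- segment_bins(sim$table, k = length(unique(sim$truth)), seed = 1)
#' fit
#' @export
segment_bins <- function(x, mode = c("hybrid", "global", "local"), k = NULL,
                         k_range = 2:12, tau = 0.99, seed = NULL,
                         model = NULL, ...) {
  mode <- match.arg(mode)
  validate_bin_table(x)
  features <- build_feature_matrix(x)
  if (mode == "local") {
    if (is.null(model)) {
      stop("mode = \"local\" decodes an existing mixture: supply 'model' ",
           "or use mode = \"hybrid\"", call. = FALSE)
    }
  } else if (is.null(model)) {
    if (is.null(k)) {
      k <- as.integer(select_k(features, min(k_range), min(max(k_range), nrow(features)),
                               seed = seed, ...))
    }
    model <- fit_global_gmm(features, k, seed = seed, ...)
  }
  clustering <- switch(mode,
    global = model$clustering,
    hybrid = ,
    local = as.integer(local_decode_hmm(x, model, tau = tau))
  )
  out <- x
  out$cluster <- clustering
  structure(
    list(table = out, model = model, clustering = clustering,
         segments = segments_from_clustering(out),
         mode = mode, k = model$k, tau = tau, seed = seed),
    class = "cna_fit"
  )
}

#' Hybrid global-then-local segmentation
#'
#' Convenience wrapper for `segment_bins(x, mode = "hybrid", ...)`: fits the
#' global Gaussian mixture and decodes it locally along the genome.
#'
#' @inheritParams segment_bins
#' @return A `cna_fit`; see [segment_bins()].
#' @export
hybrid_segment <- function(x, k, tau = 0.99, seed = NULL, ...) {
  segment_bins(x, mode = "hybrid", k = k, tau = tau, seed = seed, ...)
}

#' @export
print.cna_fit <- function(x, ...) {
  cat(sprintf("CNA segmentation (%s mode): k = %d, n = %d bins, m = %d sample%s\n",
              x$mode, x$k, nrow(x$table$bins), length(x$table$samples),
              if (length(x$table$samples) == 1) "" else "s"))
  if (x$mode != "global") cat(sprintf("  tau = %g\n", x$tau))
  cat(sprintf("  %d segments over %d chromosomes; GMM log-likelihood %.3f\n",
              nrow(x$segments), length(unique(x$table$bins$chrom)),
              x$model$loglik))
  invisible(x)
}

#' @export
summary.cna_fit <- function(object, ...) {
  sizes <- table(factor(object$clustering))
  cent <- compute_centroids(object$table)
  out <- list(fit = object, sizes = sizes, centroids = cent)
  class(out) <- "summary.cna_fit"
  out
}

#' @export
print.summary.cna_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCluster sizes:\n")
  print(x$sizes)
  cat("\nCentroids (per-sample mean RDR / BAF):\n")
  print(as.data.frame(x$centroids), digits = 4)
  invisible(x)
}

#' @export
coef.cna_fit <- function(object, ...) {
  means <- object$model$means
  rownames(means) <- paste0("cluster", seq_len(nrow(means)) - 1L)
  means
}

#' @export
fitted.cna_fit <- function(object, ...) object$clustering

#' Plot a segmentation in RDR / allelic-imbalance space
#'
#' Scatter of bins for one sample with allelic imbalance (`0.5 - BAF`) on the
#' x-axis and RDR on the y-axis, coloured by cluster — the standard view for
#' judging whether clusters are homogeneous and well separated.
#'
#' @param x a `cna_fit`.
#' @param sample sample index or name to display.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.cna_fit <- function(x, sample = 1, ...) {
  tb <- x$table
  p <- if (is.character(sample)) match(sample, tb$samples) else as.integer(sample)
  if (is.na(p) || p < 1 || p > length(tb$samples)) {
    stop("unknown sample", call. = FALSE)
  }
  cl <- x$clustering
  cols <- grDevices::hcl.colors(max(cl) + 2L, "Dark 3")[cl + 1L]
  graphics::plot(allelic_imbalance(tb$baf[, p]), tb$rdr[, p],
                 col = cols, pch = 16, cex = 0.6,
                 xlab = "allelic imbalance (0.5 - BAF)", ylab = "RDR",
                 main = sprintf("sample %s", tb$samples[p]), ...)
  invisible(x)
}
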