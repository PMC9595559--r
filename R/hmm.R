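# Local segmentation: Viterbi decoding of a hidden Markov model whose states
# are the fitted mixture components. The transition matrix has self-transition
# probability tau and uniform off-diagonal mass (1 - tau) / (k - 1); the
# initial distribution is uniform. A high tau encodes the prior that CNAs
# affect large genomic segments, smoothing isolated outlier bins into their
# surrounding run. Decoding restarts at every chromosome boundary, so bins on
# different chromosomes never constrain each other.

# Viterbi over one chromosome block; logdens is T x k, log-space throughout.
# Ties in back-pointers and in the terminal state break toward the lower
# component index (which.max returns the first maximum).
viterbi_block <- function(logdens, log_trans) {
  T_len <- nrow(logdens)
  k <- ncol(logdens)
  psi <- matrix(0L, T_len, k)
  delta <- -log(k) + logdens[1, ]
  if (T_len > 1) {
    for (t in 2:T_len) {
      scores <- delta + log_trans  # scores[i, j]: from state i to state j
      psi[t, ] <- apply(scores, 2, which.max)
      delta <- scores[cbind(psi[t, ], seq_len(k))] + logdens[t, ]
    }
  }
  path <- integer(T_len)
  path[T_len] <- which.max(delta)
  if (T_len > 1) {
    for (t in (T_len - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

# log joint probability of a given state path under the HmmSpec (uniform
# initial distribution, fixed-tau transitions, component emissions)
hmm_path_logprob <- function(logdens_blocks, paths, log_trans, k) {
  total <- 0
  for (b in seq_along(paths)) {
    path <- paths[[b]]
    ld <- logdens_blocks[[b]]
    total <- total - log(k) + ld[1, path[1]]
    if (length(path) > 1) {
      for (t in 2:length(path)) {
        total <- total + log_trans[path[t - 1], path[t]] + ld[t, path[t]]
      }
    }
  }
  total
}

#' Local segmentation by HMM decoding of fitted mixture components
#'
#' Builds a hidden Markov model whose k states emit from the components of a
#' fitted Gaussian mixture, with self-transition probability `tau`, uniform
#' off-diagonal transitions `(1 - tau) / (k - 1)` and a uniform initial
#' distribution, then Viterbi-decodes each chromosome independently. With
#' `tau` near 1 the decoding smooths over isolated outlier bins; at
#' `tau = 1/k` transitions are uniform and the decoding reduces to per-bin
#' maximum-likelihood component assignment.
#'
#' @param x a [bin_table()].
#' @param model a `cna_gmm` fitted on this table's features (its component
#'   dimension must equal `2m`).
#' @param tau self-transition probability in `(0, 1)`.
#' @return integer vector of 0-based cluster labels, one per bin; the Viterbi
#'   log joint probability is attached as attribute `"logprob"`.
#' @export
local_decode_hmm <- function(x, model, tau = 0.99) {
  stopifnot(inherits(x, "bin_table"), inherits(model, "cna_gmm"))
  if (!is_prob(tau) || tau <= 0 || tau >= 1) {
    stop("'tau' must lie strictly between 0 and 1", call. = FALSE)
  }
  features <- build_feature_matrix(x)
  if (ncol(features) != model$d) {
    stop(sprintf("model dimension %d does not match table feature dimension %d",
                 model$d, ncol(features)), call. = FALSE)
  }
  k <- model$k
  n <- nrow(features)
  if (k == 1) {
    return(structure(rep(0L, n), logprob = sum(gmm_log_density(model, features))))
  }
  log_trans <- matrix(log((1 - tau) / (k - 1)), k, k)
  diag(log_trans) <- log(tau)
  logdens <- gmm_log_density(model, features)
  labels <- integer(n)
  blocks <- split(seq_len(n), factor(x$bins$chrom, levels = unique(x$bins$chrom)))
  logdens_blocks <- lapply(blocks, function(idx) logdens[idx, , drop = FALSE])
  paths <- lapply(logdens_blocks, viterbi_block, log_trans = log_trans)
  for (b in seq_along(blocks)) labels[blocks[[b]]] <- paths[[b]] - 1L
  structure(labels,
            logprob = hmm_path_logprob(logdens_blocks, paths, log_trans, k))
}
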