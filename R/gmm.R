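# Global segmentation: Gaussian mixture model fitted by EM in the joint
# 2m-dimensional RDR/BAF feature space. Written against the usual EM recipe
# with k-means++ seeding, multiple restarts and a variance floor; diagonal
# covariance is the default because RDR and BAF noise scales differ and full
# covariance overfits at small k.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# n x k matrix of per-component Gaussian log densities (no mixing weights)
gmm_log_density <- function(model, features) {
  n <- nrow(features)
  k <- model$k
  out <- matrix(NA_real_, n, k)
  if (model$covariance == "diagonal") {
    for (j in seq_len(k)) {
      v <- model$vars[j, ]
      centered <- sweep(features, 2, model$means[j, ])
      out[, j] <- -0.5 * (sum(log(2 * pi * v)) +
                            rowSums(sweep(centered^2, 2, v, "/")))
    }
  } else {
    for (j in seq_len(k)) {
      R <- chol(model$covs[[j]])
      centered <- sweep(features, 2, model$means[j, ])
      z <- backsolve(R, t(centered), transpose = TRUE)
      out[, j] <- -0.5 * (ncol(features) * log(2 * pi) +
                            2 * sum(log(diag(R))) + colSums(z^2))
    }
  }
  out
}

# squared Euclidean distance from each row of x to each center (rows)
sqdist_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 1, rowSums(x^2), "+"), 2, rowSums(centers^2), "+")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

em_once <- function(x, k, covariance, max_iter, tol, var_floor) {
  n <- nrow(x)
  d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  # hard-assignment initialisation: moments of the nearest-center partition.
  # Initialising all components at the pooled variance lets nearby clusters
  # collapse symmetrically onto their midpoint; per-cluster moments do not.
  assign <- max.col(-sqdist_to_centers(x, centers), ties.method = "first")
  nj0 <- tabulate(assign, k)
  if (any(nj0 == 0)) return(NULL)  # starved center: caller re-seeds
  means <- matrix(0, k, d)
  vars <- matrix(0, k, d)
  for (j in seq_len(k)) {
    member <- x[assign == j, , drop = FALSE]
    means[j, ] <- colMeans(member)
    vars[j, ] <- pmax(colMeans(member^2) - means[j, ]^2, var_floor)
  }
  covs <- if (covariance == "full") {
    lapply(seq_len(k), function(j) diag(vars[j, ], d))
  } else {
    NULL
  }
  model <- list(k = k, d = d, covariance = covariance, weights = nj0 / n,
                means = means, vars = vars, covs = covs)
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- sweep(gmm_log_density(model, x), 2, log(model$weights), "+")
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    # EM guarantees a non-decreasing likelihood; a real drop is a defect
    if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev))) {
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    }
    resp <- exp(lp - lse)
    nj <- colSums(resp)
    if (any(nj < 1e-8)) return(NULL)  # degenerate component: caller re-inits
    model$weights <- nj / n
    model$means <- sweep(t(resp) %*% x, 1, nj, "/")
    if (covariance == "diagonal") {
      ex2 <- sweep(t(resp) %*% x^2, 1, nj, "/")
      model$vars <- pmax(ex2 - model$means^2, var_floor)
    } else {
      for (j in seq_len(k)) {
        centered <- sweep(x, 2, model$means[j, ])
        model$covs[[j]] <- crossprod(centered * sqrt(resp[, j])) / nj[j] +
          diag(var_floor, d)
      }
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  model$loglik <- ll_prev
  model$n_iter <- iter
  model
}

#' Fit a Gaussian mixture model for global segmentation
#'
#' Global segmentation pools bins genome-wide, ignoring genomic position:
#' bins are clustered in the joint 2m-dimensional RDR/BAF feature space by a
#' k-component Gaussian mixture fitted with EM. Each bin is labelled by its
#' maximum-responsibility component, so bins with similar copy-number signal
#' anywhere in the genome share a cluster.
#'
#' Initialisation uses k-means++ seeding; `n_restarts` independent restarts
#' are run from the given seed and the best log-likelihood kept, which makes
#' the fit deterministic given `seed`. A degenerate restart (a component
#' losing all responsibility) is discarded; if every restart degenerates the
#' fit fails with an error. Responsibility ties break toward the lower
#' component index.
#'
#' @param features `n x 2m` matrix from [build_feature_matrix()].
#' @param k number of mixture components (`1 <= k <= n`).
#' @param seed integer seed controlling initialisation.
#' @param covariance `"diagonal"` (default) or `"full"` component covariance.
#' @param n_restarts number of k-means++ restarts (best likelihood kept).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param var_floor lower bound on per-dimension variances, guarding against
#'   collapse onto duplicated points.
#' @return An object of class `cna_gmm`: component `weights`, `means`
#'   (`k x 2m`), variances (diagonal) or covariance matrices (full), the final
#'   `loglik`, `bic`, and `clustering` — 0-based cluster labels, one per bin.
#' @export
fit_global_gmm <- function(features, k, seed = NULL,
                           covariance = c("diagonal", "full"),
                           n_restarts = 10, max_iter = 500, tol = 1e-8,
                           var_floor = 1e-6) {
  covariance <- match.arg(covariance)
  features <- as.matrix(features)
  n <- nrow(features)
  if (!is_count(k)) stop("'k' must be a positive integer", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the number of bins n = %d", k, n),
                  call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- em_once(features, k, covariance, max_iter, tol, var_floor)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("GMM fit failed: every restart produced a degenerate component",
         call. = FALSE)
  }
  d <- ncol(features)
  n_par <- (k - 1) + k * d +
    if (covariance == "diagonal") k * d else k * d * (d + 1) / 2
  best$df <- n_par
  best$bic <- -2 * best$loglik + n_par * log(n)
  lp <- sweep(gmm_log_density(best, features), 2, log(best$weights), "+")
  best$clustering <- max.col(lp, ties.method = "first") - 1L
  best$n <- n
  class(best) <- "cna_gmm"
  best
}

#' @export
print.cna_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%s covariance): k = %d, d = %d, n = %d\n",
              x$covariance, x$k, x$d, x$n))
  cat(sprintf("  log-likelihood %.3f, BIC %.3f, %d EM iterations\n",
              x$loglik, x$bic, x$n_iter))
  invisible(x)
}

#' @export
logLik.cna_gmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' Choose the number of clusters by BIC
#'
#' Fits [fit_global_gmm()] for each candidate k and returns the k minimising
#' the Bayesian information criterion (ties break toward the smaller k). The
#' underlying problem takes k as given; this criterion serves unattended runs.
#'
#' @inheritParams fit_global_gmm
#' @param k_min,k_max candidate range, `1 <= k_min <= k_max <= n`.
#' @return integer k; the BIC values are attached as attribute `"bic"`.
#' @export
select_k <- function(features, k_min, k_max, seed = NULL, ...) {
  n <- nrow(features)
  if (!is_count(k_min) || !is_count(k_max) || k_min > k_max || k_max > n) {
    stop(sprintf("need 1 <= k_min <= k_max <= n (got k_min = %s, k_max = %s, n = %d)",
                 k_min, k_max, n), call. = FALSE)
  }
  ks <- k_min:k_max
  bics <- vapply(ks, function(k) fit_global_gmm(features, k, seed = seed, ...)$bic,
                 numeric(1))
  structure(ks[which.min(bics)], bic = stats::setNames(bics, ks))
}
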