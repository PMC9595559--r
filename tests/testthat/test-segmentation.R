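test_that("the feature matrix concatenates RDR and BAF blocks per sample", {
  tb <- toy_table()
  f <- build_feature_matrix(tb)
  expect_equal(dim(f), c(3, 4))
  expect_equal(colnames(f), c("RDR.A", "RDR.B", "BAF.A", "BAF.B"))
  expect_equal(f[1, ], c(RDR.A = 1.0, RDR.B = 0.9, BAF.A = 0.5, BAF.B = 0.48))
  # identical bins give identical rows
  tb2 <- line_table(c(1.2, 1.2), baf = c(0.4, 0.4))
  f2 <- build_feature_matrix(tb2)
  expect_equal(f2[1, ], f2[2, ])
  expect_equal(unname(f2[1, ]), c(1.2, 0.4))
})

test_that("the GMM recovers two planted point clouds exactly", {
  set.seed(5)
  n <- 100
  f <- rbind(cbind(rnorm(n, 1.0, 0.01), rnorm(n, 0.5, 0.01)),
             cbind(rnorm(n, 3.0, 0.01), rnorm(n, 0.1, 0.01)))
  planted <- rep(0:1, each = n)
  fit <- fit_global_gmm(f, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(planted, fit$clustering), 1)
  # cross-check against an independent mixture implementation
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  mc <- mclust::Mclust(f, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(adjusted_rand_index(mc$classification, fit$clustering), 1)
})

test_that("the GMM fit is deterministic given the seed and handles k = 1", {
  set.seed(8)
  f <- cbind(rnorm(60), rnorm(60))
  a <- fit_global_gmm(f, k = 3, seed = 42)
  b <- fit_global_gmm(f, k = 3, seed = 42)
  expect_identical(a$clustering, b$clustering)
  expect_identical(a$means, b$means)
  one <- fit_global_gmm(f, k = 1, seed = 1)
  expect_equal(unique(one$clustering), 0L)
  expect_error(fit_global_gmm(f, k = 61, seed = 1), "exceeds")
})

test_that("duplicate feature rows always share a GMM label", {
  set.seed(2)
  f <- cbind(c(rnorm(30, 0), rnorm(30, 4), 1.7, 1.7),
             c(rnorm(30, 0), rnorm(30, 4), 2.0, 2.0))
  fit <- fit_global_gmm(f, k = 2, seed = 3)
  expect_equal(fit$clustering[61], fit$clustering[62])
})

test_that("full-covariance components are supported", {
  set.seed(9)
  rot <- matrix(c(1, 0.9, 0.9, 1), 2)
  f <- rbind(matrix(rnorm(200), ncol = 2) %*% chol(rot),
             sweep(matrix(rnorm(200, sd = 0.2), ncol = 2), 2, c(5, 5), "+"))
  fit <- fit_global_gmm(f, k = 2, seed = 1, covariance = "full")
  expect_equal(adjusted_rand_index(rep(1:2, each = 100), fit$clustering), 1)
})

test_that("BIC selects the planted number of clusters", {
  set.seed(5)
  f2 <- rbind(cbind(rnorm(100, 1, 0.01), rnorm(100, 0.5, 0.01)),
              cbind(rnorm(100, 3, 0.01), rnorm(100, 0.1, 0.01)))
  expect_equal(as.integer(select_k(f2, 1, 5, seed = 1)), 2L)
  f1 <- cbind(rnorm(150, 1, 0.05), rnorm(150, 0.4, 0.05))
  expect_equal(as.integer(select_k(f1, 1, 4, seed = 1)), 1L)
  expect_error(select_k(f1, 3, 2, seed = 1), "k_min")
})

test_that("Viterbi decoding reproduces planted piecewise-constant runs", {
  set.seed(13)
  truth <- rep(c(0L, 1L, 0L), each = 40)
  rdr <- c(rnorm(40, 1.0, 0.03), rnorm(40, 2.0, 0.03), rnorm(40, 1.0, 0.03))
  baf <- c(rnorm(40, 0.50, 0.01), rnorm(40, 0.33, 0.01), rnorm(40, 0.50, 0.01))
  tb <- line_table(rdr, baf = pmin(baf, 0.5))
  model <- fit_global_gmm(build_feature_matrix(tb), k = 2, seed = 1)
  labels <- local_decode_hmm(tb, model, tau = 0.99)
  expect_equal(adjusted_rand_index(truth, as.integer(labels)), 1)
  runs <- rle(as.integer(labels))
  expect_equal(runs$lengths, rep(40L, 3))
})

test_that("a high self-transition absorbs an isolated outlier bin", {
  set.seed(77)
  # one bin leaning toward the distant component, inside a long run
  rdr <- c(rnorm(25, 1, 0.1), 1.58, rnorm(25, 1, 0.1), rnorm(30, 2, 0.1))
  tb <- line_table(rdr, baf = rep(0.4, length(rdr)))
  f <- build_feature_matrix(tb)
  model <- fit_global_gmm(f, k = 2, seed = 1)
  # per-bin ML puts the outlier with the far component...
  ml <- max.col(cnaseg:::gmm_log_density(model, f), ties.method = "first")
  expect_false(ml[26] == ml[25])
  # ...but a near-1 self-transition absorbs it into the surrounding run
  smoothed <- local_decode_hmm(tb, model, tau = 0.999)
  loose <- local_decode_hmm(tb, model, tau = 0.5)
  expect_equal(length(rle(as.integer(smoothed))$lengths), 2)
  expect_gt(length(rle(as.integer(loose))$lengths), 2)
  # optimality: under tau = 0.999 the smoothed path dominates the loose one
  k <- 2
  log_trans <- matrix(log(0.001), k, k)
  diag(log_trans) <- log(0.999)
  ld <- cnaseg:::gmm_log_density(model, f)
  lp_loose <- cnaseg:::hmm_path_logprob(list(ld), list(as.integer(loose) + 1L),
                                        log_trans, k)
  expect_gte(attr(smoothed, "logprob"), lp_loose)
})

test_that("uniform transitions reduce decoding to per-bin ML assignment", {
  set.seed(21)
  rdr <- runif(50, 0.8, 2.2)
  tb <- line_table(rdr)
  model <- fit_global_gmm(build_feature_matrix(tb), k = 2, seed = 1)
  labels <- local_decode_hmm(tb, model, tau = 1 / 2)
  ml <- max.col(cnaseg:::gmm_log_density(model, build_feature_matrix(tb)),
                ties.method = "first") - 1L
  expect_equal(as.integer(labels), ml)
})

test_that("the Viterbi path beats the per-bin argmax path when tau >= 1/k", {
  set.seed(31)
  rdr <- c(rnorm(30, 1, 0.2), rnorm(30, 1.6, 0.2))
  tb <- line_table(rdr)
  f <- build_feature_matrix(tb)
  model <- fit_global_gmm(f, k = 2, seed = 1)
  for (tau in c(0.6, 0.9, 0.99)) {
    vit <- local_decode_hmm(tb, model, tau = tau)
    ld <- cnaseg:::gmm_log_density(model, f)
    argmax_path <- max.col(ld, ties.method = "first")
    k <- 2
    log_trans <- matrix(log((1 - tau) / (k - 1)), k, k)
    diag(log_trans) <- log(tau)
    lp_argmax <- cnaseg:::hmm_path_logprob(list(ld), list(argmax_path), log_trans, k)
    expect_gte(attr(vit, "logprob"), lp_argmax)
  }
})

test_that("decoding restarts at chromosome boundaries", {
  # the same state pattern on two chromosomes decodes without cross-talk:
  # a short run at the start of chr2 is not absorbed into chr1's long run
  rdr <- c(rep(1.0, 30), rep(2.0, 3), rep(1.0, 27))
  chrom <- rep(c("1", "2"), each = 30)
  tb <- line_table(rdr, chrom = chrom)
  model <- fit_global_gmm(build_feature_matrix(tb), k = 2, seed = 1)
  labels <- as.integer(local_decode_hmm(tb, model, tau = 0.999))
  expect_equal(labels[31:33], rep(labels[31], 3))
  expect_false(labels[31] == labels[30])
})

test_that("hybrid segmentation recovers planted clusters on simulated data", {
  sim <- simulate_bins(simulation_config(seed = 7))
  k <- length(unique(sim$truth))
  fit <- segment_bins(sim$table, k = k, seed = 7)
  expect_gte(adjusted_rand_index(sim$truth, fit$clustering), 0.9)
  expect_lte(length(unique(fit$clustering)), k)
  # noiseless limit: perfect separability
  sim0 <- simulate_bins(simulation_config(seed = 7, rdr_noise_sd = 0,
                                          baf_coverage = Inf))
  fit0 <- segment_bins(sim0$table, k = k, seed = 7)
  expect_equal(adjusted_rand_index(sim0$truth, fit0$clustering), 1)
})

test_that("the fit object carries methods and a consistent segment list", {
  sim <- simulate_bins(simulation_config(seed = 2, bins_per_chrom = 100,
                                         n_segments = 8))
  fit <- segment_bins(sim$table, k = length(unique(sim$truth)), seed = 2)
  expect_s3_class(fit, "cna_fit")
  expect_output(print(fit), "CNA segmentation")
  s <- summary(fit)
  expect_output(print(s), "Centroids")
  expect_equal(nrow(coef(fit)), fit$k)
  expect_identical(fitted(fit), fit$clustering)
  expect_equal(sum(fit$segments$n_bins), nrow(sim$table$bins))
  grDevices::pdf(NULL)
  expect_silent(plot(fit))
  grDevices::dev.off()
  # mode = "local" requires a model
  expect_error(segment_bins(sim$table, mode = "local"), "model")
  lab_local <- segment_bins(sim$table, mode = "local", model = fit$model)$clustering
  expect_identical(lab_local, fit$clustering)
})
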