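#' Joint RDR/BAF feature matrix
#'
#' Represents each bin as a vector in 2m-dimensional space by concatenating
#' its m read-depth ratios and m B-allele frequencies across samples:
#' `v_i = [RDR(1,i), ..., RDR(m,i), BAF(1,i), ..., BAF(m,i)]`. Euclidean
#' distances between rows drive clustering, analytics and editing.
#'
#' @param x a [bin_table()].
#' @param scale if `TRUE`, z-scale each column. Off by default: clustering is
#'   performed on native RDR/BAF scales, so centroid-threshold semantics in
#'   merge/absorb operations stay in data units.
#' @return numeric `n x 2m` matrix with column names `RDR.<sample>`,
#'   `BAF.<sample>`.
#' @export
build_feature_matrix <- function(x, scale = FALSE) {
  stopifnot(inherits(x, "bin_table"))
  f <- cbind(x$rdr, x$baf)
  colnames(f) <- c(paste0("RDR.", x$samples), paste0("BAF.", x$samples))
  if (scale) {
    sds <- apply(f, 2, stats::sd)
    sds[sds == 0] <- 1
    f <- sweep(sweep(f, 2, colMeans(f)), 2, sds, "/")
  }
  f
}

#' Allelic imbalance transform
#'
#' Converts a B-allele frequency into allelic imbalance, `0.5 - BAF`: 0 means
#' allelic balance (heterozygous diploid), 0.5 means complete loss of one
#' allele.
#'
#' @param baf numeric vector with values in `[0, 0.5]`.
#' @return `0.5 - baf`.
#' @export
allelic_imbalance <- function(baf) {
  if (any(baf < 0 | baf > 0.5, na.rm = TRUE)) {
    stop("BAF must lie in [0, 0.5]", call. = FALSE)
  }
  0.5 - baf
}
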