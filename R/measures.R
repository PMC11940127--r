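#' Gaussian copula transform
#'
#' Maps a series to standard-normal marginals through its empirical ranks:
#' each value is replaced by `qnorm(rank / (T + 1))`, ties broken by average
#' rank. The output depends on the input only through its ordering, so any
#' strictly increasing transform of the input yields an identical result.
#' This is the first step of the Gaussian-copula lower-bound estimator of
#' mutual-information-type quantities.
#'
#' @param x Numeric vector with at least 8 samples and non-zero variance.
#' @return Numeric vector of the same length with standard-normal marginals.
#' @examples
#' copula_transform(c(10, -5, 7, 2, 0, 1, 3, 9))
#' @export
copula_transform <- function(x) {
  if (length(x) < 8L) stop("copula transform needs at least 8 samples")
  if (anyNA(x) || !all(is.finite(x))) stop("input contains non-finite values")
  if (max(x) == min(x))
    stop("degenerate input: series is constant (zero variance)")
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# Row-wise copula transform of a channels x time matrix.
copula_rows <- function(data) {
  t(apply(data, 1L, copula_transform))
}

#' Copula correlation matrix
#'
#' Copula-transforms each row (channel) of a channels x time matrix and
#' returns the Pearson correlation matrix of the transformed rows. All
#' subset measures ([total_correlation()], [dual_total_correlation()],
#' [o_information()]) are functions of this matrix alone.
#'
#' @param data A channels x time matrix.
#' @return A k x k correlation matrix.
#' @export
copula_correlation <- function(data) {
  if (is.null(dim(data)) || nrow(data) < 2L)
    stop("data must be a matrix with at least 2 rows (channels)")
  if (ncol(data) <= nrow(data))
    stop("need more time samples than channels")
  stats::cor(t(copula_rows(data)))
}

#' Joint entropy of a multivariate Gaussian
#'
#' Closed-form differential entropy, in bits, of a k-variate Gaussian with
#' correlation matrix `R` and unit variances:
#' `H = 0.5 * log2((2*pi*e)^k * det(R))`.
#'
#' @param R Symmetric positive-definite correlation matrix (unit diagonal).
#' @return Entropy in bits.
#' @export
gaussian_joint_entropy <- function(R) {
  R <- as.matrix(R)
  k <- nrow(R)
  if (k != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop("R must be a symmetric square matrix")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have a unit diagonal")
  0.5 * (k * log2(2 * pi * exp(1)) + log2_det(R))
}

# log2 determinant via Cholesky, with a single ridge retry for near-singular
# matrices (trial-averaged band-limited channels can be close to collinear).
log2_det <- function(R, ridge = 1e-10) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(R + diag(ridge, nrow(R))), error = function(e) NULL)
    if (is.null(ch))
      stop("correlation matrix is not positive definite (even after ridge)")
  }
  2 * sum(log2(diag(ch)))
}

# Measures from a (full) copula correlation matrix restricted to `subset`.
# This is the computational core shared by the exported estimators and the
# greedy search, which reuses one full correlation matrix per participant.
measure_from_correlation <- function(R, subset = seq_len(nrow(R)),
                                     measure = c("TC", "DTC", "O", "negO")) {
  measure <- match.arg(measure)
  k <- length(subset)
  if (k < 2L) stop("subset must contain at least 2 channels")
  Rs <- R[subset, subset, drop = FALSE]
  if (qr(Rs)$rank < k)
    stop("rank-deficient correlation matrix for subset {",
         paste(subset, collapse = ","), "} (collinear channels)")
  ld <- tryCatch(log2_det(Rs), error = function(e)
    stop("rank-deficient correlation matrix for subset {",
         paste(subset, collapse = ","), "}: ", conditionMessage(e)))
  tc <- -0.5 * ld
  if (measure == "TC") return(tc)
  ld_minors <- vapply(seq_len(k), function(j)
    log2_det(Rs[-j, -j, drop = FALSE]), numeric(1))
  dtc <- 0.5 * (sum(ld_minors) - (k - 1) * ld)
  switch(measure, DTC = dtc, O = tc - dtc, negO = -(tc - dtc))
}

#' Total correlation (TC) of a channel subset
#'
#' Gaussian-copula lower-bound estimate of the total correlation, the sum of
#' marginal entropies minus the joint entropy. After the copula transform the
#' marginals are standard normal, so `TC = -0.5 * log2(det(R))` with `R` the
#' copula correlation matrix. TC accumulates the collective constraints (the
#' "redundant-flavoured" shared information) of the subset and is
#' non-negative up to numerical tolerance.
#'
#' @param data A k x T matrix (k >= 2 channels, T > k time samples).
#' @return TC in bits.
#' @export
total_correlation <- function(data) {
  measure_from_correlation(copula_correlation(data), measure = "TC")
}

#' Dual total correlation (DTC) of a channel subset
#'
#' Gaussian-copula lower-bound estimate of the dual total correlation
#' (binding information): the joint entropy minus the summed conditional
#' entropies, which on the copula correlation matrix `R` reduces to
#' `0.5 * (sum_j log2 det(R[-j,-j]) - (k - 1) * log2 det(R))`. DTC measures
#' the shared randomness (complementary information) of the subset.
#'
#' @inheritParams total_correlation
#' @return DTC in bits.
#' @export
dual_total_correlation <- function(data) {
  measure_from_correlation(copula_correlation(data), measure = "DTC")
}

#' O-information of a channel subset
#'
#' The difference `TC - DTC`, computed on the same copula correlation matrix.
#' Positive values indicate a redundancy-dominated subset (information is
#' replicated across channels); negative values a synergy-dominated subset
#' (information is only available jointly). Identically zero for pairs.
#'
#' @inheritParams total_correlation
#' @return O-information in bits.
#' @export
o_information <- function(data) {
  measure_from_correlation(copula_correlation(data), measure = "O")
}

#' Normalize an information value by interaction order
#'
#' Divides a measure value by the number of channels in its subset, making
#' values comparable across interaction orders.
#'
#' @param value Measure value in bits.
#' @param order Interaction order k (>= 2).
#' @return Bits per channel.
#' @export
normalize_by_order <- function(value, order) {
  if (any(order < 2L)) stop("interaction order must be >= 2")
  value / order
}
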