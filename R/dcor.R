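#' Pairwise Euclidean distance matrix
#'
#' Computes the full \eqn{n \times n} Euclidean distance matrix between the
#' rows of a sample matrix. This is the first step of the distance-correlation
#' V-statistic: samples may live in arbitrary dimension, which is what makes
#' dCor usable between a low-dimensional bias variable and a wide feature
#' matrix.
#'
#' @param x Numeric matrix (n samples by d coordinates) or a vector, which is
#'   treated as a single-column matrix. All entries must be finite and
#'   \code{n >= 2}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
#' @examples
#' pairwise_distances(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
pairwise_distances <- function(x) {
  x <- as_sample_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples for a distance matrix")
  bad <- which(!apply(x, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("non-finite values in sample row(s): ", paste(bad, collapse = ", "))
  }
  as.matrix(stats::dist(x))
}

as_sample_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

#' Double-center a distance matrix
#'
#' V-statistic double centering: \eqn{A_{jk} = d_{jk} - \bar d_{j.} - \bar
#' d_{.k} + \bar d_{..}}. The result has row and column means of zero and is
#' the building block of distance covariance.
#'
#' @param d Symmetric numeric matrix with zero diagonal (a distance matrix).
#' @param w Optional nonnegative sample weights. When supplied the centering
#'   uses weighted means (\eqn{H_w = I - \mathbf{1} w^T / W}), which makes a
#'   sample with weight 2 exactly equivalent to the same sample duplicated.
#' @return Centered matrix of the same dimension.
#' @export
double_center <- function(d, w = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  n <- nrow(d)
  if (is.null(w)) {
    rm_ <- rowMeans(d)
    cm_ <- colMeans(d)
    gm <- mean(d)
    d - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  } else {
    w <- check_weights(w, n)
    W <- sum(w)
    rw <- as.vector(d %*% w) / W       # weighted row means
    cw <- as.vector(crossprod(w, d)) / W
    gw <- sum(w * rw) / W
    d - outer(rw, rep(1, n)) - outer(rep(1, n), cw) + gw
  }
}

check_weights <- function(w, n) {
  w <- as.numeric(w)
  if (length(w) != n) stop("weight vector length must match sample count")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and nonnegative")
  if (sum(w) <= 0) stop("weights must not all be zero")
  w
}

#' Squared distance covariance from centered matrices
#'
#' \eqn{V^2 = n^{-2} \sum_{jk} A_{jk} B_{jk}} for two double-centered distance
#' matrices of the same size. Nonnegativity is guaranteed only for
#' \code{a == b} (a distance variance).
#'
#' @param a,b Double-centered distance matrices of equal dimension.
#' @param w Optional weights; with weights the statistic is
#'   \eqn{W^{-2}\sum_{jk} w_j w_k A_{jk} B_{jk}}.
#' @return Scalar.
#' @export
distance_covariance_sq <- function(a, b, w = NULL) {
  if (!all(dim(a) == dim(b))) stop("centered matrices must have equal dimensions")
  n <- nrow(a)
  if (is.null(w)) {
    sum(a * b) / n^2
  } else {
    w <- check_weights(w, n)
    ww <- outer(w, w)
    sum(ww * a * b) / sum(w)^2
  }
}

#' Squared distance correlation
#'
#' The squared sample distance correlation between two multivariate samples,
#' \deqn{DC^2(B, F) = \frac{V^2(B, F)}{\sqrt{V^2(B, B)\, V^2(F, F)}}}
#' computed with the biased V-statistic (double-centered distance matrices).
#' When the product of distance variances does not exceed \code{eps} (e.g. a
#' constant sample) the statistic is defined as 0. The result is clamped to
#' \eqn{[0, 1]} against floating-point drift.
#'
#' dCor detects linear and nonlinear dependence alike and is zero (in
#' population) iff the variables are independent, which is what makes it a
#' usable decorrelation penalty between network features and a bias variable.
#'
#' @param b,f Sample matrices (or vectors) with the same number of rows,
#'   \code{n >= 2}.
#' @param eps Denominator guard, default \code{1e-12}.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20)
#' distance_correlation_sq(x, 3 * x + 7)   # affine image: 1
distance_correlation_sq <- function(b, f, eps = 1e-12) {
  weighted_distance_correlation_sq(b, f, w = NULL, eps = eps)
}

#' Sample-weighted squared distance correlation
#'
#' Weighted V-statistic variant of [distance_correlation_sq()]: both the
#' double centering and the covariance sums use the weights, so uniform
#' weights recover the unweighted statistic exactly and duplicating a sample
#' is equivalent to doubling its weight. Used to decorrelate control features
#' equally from scanners of very different cohort sizes.
#'
#' @inheritParams distance_correlation_sq
#' @param w Nonnegative weights of length n (sum > 0), or \code{NULL} for the
#'   unweighted statistic.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
weighted_distance_correlation_sq <- function(b, f, w = NULL, eps = 1e-12) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  b <- as_sample_matrix(b); f <- as_sample_matrix(f)
  if (nrow(b) != nrow(f)) stop("b and f must have the same number of samples")
  if (nrow(b) < 2L) stop("need at least 2 samples")
  if (!is.null(w)) w <- check_weights(w, nrow(b))
  A <- double_center(pairwise_distances(b), w)
  C <- double_center(pairwise_distances(f), w)
  vxy <- distance_covariance_sq(A, C, w)
  vxx <- distance_covariance_sq(A, A, w)
  vyy <- distance_covariance_sq(C, C, w)
  den2 <- vxx * vyy
  if (!(den2 > eps)) return(0)
  min(max(vxy / sqrt(den2), 0), 1)
}

# Value and gradient of DC^2(B, F) with respect to F. B is a constant (bias
# variables are inputs, never trained); the gradient flows through the F
# distance matrix only. Returns list(value, grad) with grad an n x d matrix.
# Zero pairwise distances contribute zero gradient (the subgradient choice).
dcor_sq_grad <- function(b, f, w = NULL, eps = 1e-12) {
  b <- as_sample_matrix(b); f <- as_sample_matrix(f)
  n <- nrow(f)
  if (!is.null(w)) w <- check_weights(w, n)
  Db <- pairwise_distances(b)
  Df <- pairwise_distances(f)
  A <- double_center(Db, w)
  C <- double_center(Df, w)
  vxy <- distance_covariance_sq(A, C, w)
  vxx <- distance_covariance_sq(A, A, w)
  vyy <- distance_covariance_sq(C, C, w)
  den2 <- vxx * vyy
  if (!(den2 > eps) || vyy <= 0) {
    return(list(value = 0, grad = matrix(0, n, ncol(f))))
  }
  den <- sqrt(den2)
  val <- vxy / den
  if (is.null(w)) {
    # d value / d C, then pull back through the (symmetric, idempotent)
    # centering projector: dV/dDf = H M H for M = dV/dC.
    M <- (A / den - (vxy / (sqrt(vxx) * vyy^1.5)) * C) / n^2
    G <- double_center(M)        # H M H (H symmetric idempotent)
  } else {
    W <- sum(w)
    ww <- outer(w, w)
    M <- (ww * A / den - (vxy / (sqrt(vxx) * vyy^1.5)) * ww * C) / W^2
    # C = Hw Df Hw' with Hw = I - 1 w'/W  =>  dV/dDf = Hw' M Hw
    Hw <- diag(n) - outer(rep(1, n), w) / W
    G <- crossprod(Hw, M) %*% Hw
  }
  # chain through D_jk = ||f_j - f_k||: dD_jk/df_j = (f_j - f_k)/D_jk
  S <- G + t(G)
  inv <- ifelse(Df > 0, 1 / pmax(Df, .Machine$double.eps), 0)
  K <- S * inv
  grad <- f * rowSums(K) - K %*% f
  dimnames(grad) <- NULL
  list(value = min(max(val, 0), 1), grad = grad)
}
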