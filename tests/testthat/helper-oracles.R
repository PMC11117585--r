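# Independent brute-force oracles, deliberately naive (explicit loops),
# against which the vectorized implementations are checked.

naive_dcov_sq <- function(x, y, w = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  W <- sum(w)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (j in 1:n) for (k in 1:n) {
    dx[j, k] <- sqrt(sum((x[j, ] - x[k, ])^2))
    dy[j, k] <- sqrt(sum((y[j, ] - y[k, ])^2))
  }
  center <- function(d) {
    a <- matrix(0, n, n)
    rw <- numeric(n); cw <- numeric(n)
    for (j in 1:n) rw[j] <- sum(w * d[j, ]) / W
    for (k in 1:n) cw[k] <- sum(w * d[, k]) / W
    g <- 0
    for (j in 1:n) for (k in 1:n) g <- g + w[j] * w[k] * d[j, k]
    g <- g / W^2
    for (j in 1:n) for (k in 1:n) a[j, k] <- d[j, k] - rw[j] - cw[k] + g
    a
  }
  ax <- center(dx); ay <- center(dy)
  s <- 0
  for (j in 1:n) for (k in 1:n) s <- s + w[j] * w[k] * ax[j, k] * ay[j, k]
  s / W^2
}

naive_dcor_sq <- function(x, y, w = NULL, eps = 1e-12) {
  vxy <- naive_dcov_sq(x, y, w)
  vxx <- naive_dcov_sq(x, x, w)
  vyy <- naive_dcov_sq(y, y, w)
  if (!(vxx * vyy > eps)) return(0)
  min(max(vxy / sqrt(vxx * vyy), 0), 1)
}

# Central finite-difference gradient of a scalar function of a matrix.
fd_grad <- function(fun, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (fun(xp) - fun(xm)) / (2 * h)
  }
  g
}
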