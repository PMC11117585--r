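test_that("pairwise distances match hand geometry and reject bad input", {
  expect_equal(pairwise_distances(matrix(c(0, 1), 2)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  d <- pairwise_distances(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(d[1, 2], 5)
  d3 <- pairwise_distances(matrix(0:2, 3))
  expect_equal(d3[upper.tri(d3)], c(1, 2, 1))
  expect_true(isSymmetric(d3))
  expect_equal(diag(d3), rep(0, 3), ignore_attr = TRUE)
  expect_error(pairwise_distances(matrix(c(0, NA), 2)), "row")
  expect_error(pairwise_distances(matrix(1, 1, 1)), "2 samples")
})

test_that("double centering removes row/column means", {
  expect_equal(double_center(matrix(c(0, 1, 1, 0), 2)),
               matrix(c(-0.5, 0.5, 0.5, -0.5), 2))
  expect_equal(double_center(matrix(0, 4, 4)), matrix(0, 4, 4))
  set.seed(7)
  x <- matrix(rnorm(30), 10)
  a <- double_center(pairwise_distances(x))
  expect_lt(max(abs(rowMeans(a))), 1e-9)
  expect_lt(max(abs(colMeans(a))), 1e-9)
  expect_error(double_center(matrix(1, 2, 3)), "square")
})

test_that("distance covariance matches hand value and the naive oracle", {
  a <- double_center(matrix(c(0, 1, 1, 0), 2))
  expect_equal(distance_covariance_sq(a, a), 0.25)
  cst <- double_center(pairwise_distances(matrix(5, 4, 1)))
  expect_equal(distance_covariance_sq(cst, cst), 0)
  set.seed(11)
  x <- matrix(rnorm(16), 8); y <- matrix(rnorm(24), 8)
  ax <- double_center(pairwise_distances(x))
  ay <- double_center(pairwise_distances(y))
  expect_equal(distance_covariance_sq(ax, ay), naive_dcov_sq(x, y),
               tolerance = 1e-12)
  expect_error(distance_covariance_sq(ax, ay[1:4, 1:4]), "equal dimensions")
})

test_that("dCor^2 analytic properties hold", {
  set.seed(3)
  x <- matrix(rnorm(20), 10)
  expect_equal(distance_correlation_sq(x, x), 1)
  # affine invariance and the constant-sample zero branch
  b <- matrix(0:9, 10)
  expect_equal(distance_correlation_sq(b, 3 * b + 7), 1)
  expect_equal(distance_correlation_sq(matrix(2, 10, 1), x), 0)
  expect_equal(distance_correlation_sq(-1.7 * x + 2, x),
               distance_correlation_sq(x, x), tolerance = 1e-9)
  # symmetry
  y <- matrix(rnorm(30), 10)
  expect_equal(distance_correlation_sq(x, y), distance_correlation_sq(y, x))
  expect_error(distance_correlation_sq(x[1, , drop = FALSE], y[1, , drop = FALSE]),
               "2 samples")
})

test_that("dCor^2 stays in [0,1] and shrinks under independence", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- matrix(rnorm(n * sample(1:4, 1)), n)
    y <- matrix(rnorm(n * sample(1:4, 1)), n)
    v <- distance_correlation_sq(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  set.seed(99)
  big <- distance_correlation_sq(matrix(rnorm(2000), 2000), matrix(rnorm(2000), 2000))
  expect_lt(big, 0.01)
})

test_that("implementation matches the naive double-loop oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    n <- sample(4:64, 1)
    d1 <- sample(1:5, 1); d2 <- sample(1:5, 1)
    x <- matrix(rnorm(n * d1), n); y <- matrix(rnorm(n * d2) + 0.3 * x[, 1], n)
    dev <- abs(distance_correlation_sq(x, y) - naive_dcor_sq(x, y))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-10)
})

test_that("weighted dCor^2 reduces to unweighted and respects replication", {
  set.seed(5)
  x <- matrix(rnorm(12), 6); y <- matrix(rnorm(18), 6)
  u <- distance_correlation_sq(x, y)
  expect_equal(weighted_distance_correlation_sq(x, y, rep(1, 6)), u)
  expect_equal(weighted_distance_correlation_sq(x, y, rep(2, 6)), u)
  # duplicated sample with w = 1 each == single sample with w = 2
  xd <- rbind(x, x[3, ]); yd <- rbind(y, y[3, ])
  w2 <- rep(1, 6); w2[3] <- 2
  expect_equal(weighted_distance_correlation_sq(xd, yd, rep(1, 7)),
               weighted_distance_correlation_sq(x, y, w2), tolerance = 1e-12)
  # weighted oracle agreement
  w <- runif(6, 0.2, 3)
  expect_equal(weighted_distance_correlation_sq(x, y, w),
               naive_dcor_sq(x, y, w), tolerance = 1e-10)
  expect_error(weighted_distance_correlation_sq(x, y, c(1, 1, -1, 1, 1, 1)),
               "nonnegative")
})

test_that("dCor^2 gradient in F matches finite differences, B held constant", {
  set.seed(8)
  b <- matrix(rnorm(4), 4)            # 4-sample toy
  f <- matrix(rnorm(8), 4)
  g <- dccnn:::dcor_sq_grad(b, f)
  expect_equal(g$value, distance_correlation_sq(b, f))
  fd <- fd_grad(function(fm) distance_correlation_sq(b, fm), f)
  expect_equal(g$grad, fd, tolerance = 1e-6)
  # weighted path
  w <- c(2, 1, 1, 0.5)
  gw <- dccnn:::dcor_sq_grad(b, f, w)
  expect_equal(gw$value, weighted_distance_correlation_sq(b, f, w))
  fdw <- fd_grad(function(fm) weighted_distance_correlation_sq(b, fm, w), f)
  expect_equal(gw$grad, fdw, tolerance = 1e-6)
  # degenerate F: zero branch, zero gradient
  g0 <- dccnn:::dcor_sq_grad(b, matrix(1, 4, 2))
  expect_equal(g0$value, 0)
  expect_equal(g0$grad, matrix(0, 4, 2))
})
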