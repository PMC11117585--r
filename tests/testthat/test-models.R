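test_that("named variants carry their published filter and fc counts", {
  a1 <- dc_architecture("classbias_dccnn")
  expect_equal(a1$conv_filters, c(32L, 64L, 128L))
  expect_equal(a1$taps, c("fc1", "fc2", "softmax"))
  a2 <- dc_architecture("scanner_dccnn")
  expect_equal(a2$conv_filters, c(32L, 16L, 16L))
  expect_equal(a2$fc_sizes, c(40L, 100L))
  expect_equal(a2$taps, c("conv1", "fc1", "fc2"))
  a3 <- dc_architecture("fe_dccnn")
  expect_equal(a3$conv_filters, c(32L, 16L, 16L, 8L, 8L))
  expect_equal(a3$fc_sizes, c(40L, 100L))
  expect_equal(a3$dropout, 0.2)
  a4 <- dc_architecture("convgru_dccnn", input_shape = c(6, 16, 16))
  expect_equal(a4$conv_filters, c(16L, 32L, 32L))
  expect_equal(a4$fc_sizes, c(1000L, 500L))
  expect_equal(a4$taps, c("conv2", "fc1"))
  expect_error(dc_architecture("custom", input_shape = c(16, 16)),
               "conv_filters")
})

test_that("parameter counts of named variants are stable golden numbers", {
  skip_on_cran()
  n1 <- dccnn:::net_param_count(build_model(dc_architecture("classbias_dccnn",
                                                            fc_sizes = c(64, 32)),
                                            seed = 1))
  n1b <- dccnn:::net_param_count(build_model(dc_architecture("classbias_dccnn",
                                                             fc_sizes = c(64, 32)),
                                             seed = 99))
  expect_identical(n1, n1b)     # independent of the init seed
  n2 <- dccnn:::net_param_count(build_model(dc_architecture("scanner_dccnn"), 1))
  n3 <- dccnn:::net_param_count(build_model(dc_architecture("fe_model"), 1))
  expect_identical(n1, 619618L)
  expect_identical(n2, 52694L)
  expect_identical(n3, 14790L)
})

test_that("forward pass is deterministic in inference mode", {
  net <- build_model(tiny_arch(), seed = 4)
  net$classes <- c("a", "b")
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  p1 <- dccnn:::net_predict(net, x)
  p2 <- dccnn:::net_predict(net, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 3))
})

test_that("feature taps flatten and concatenate in fixed order", {
  arch <- tiny_arch(taps = c("conv2", "fc1", "softmax"))
  net <- build_model(arch, seed = 5)
  x <- array(runif(24 * 24 * 4), c(24, 24, 4))
  f <- extract_features(net, x)
  # conv2 block output is 6 x 6 x 8 after two pools, fc1 is 12, softmax 2
  expect_equal(ncol(f), 6 * 6 * 8 + 12 + 2)
  expect_equal(nrow(f), 4)
  fs <- extract_features(net, x, taps = "softmax")
  expect_equal(ncol(fs), 2)
  expect_equal(unname(fs), unname(f[, (ncol(f) - 1):ncol(f)]))
  expect_error(extract_features(net, x, taps = character(0)), "empty tap")
  expect_error(extract_features(net, x, taps = "conv9"), "unknown tap")
})

test_that("ConvGRU matches an independently coded naive recurrence", {
  set.seed(31)
  h <- 5; w <- 4; Tn <- 3; hc <- 2
  gp <- convgru_params(hc, h, w)
  x <- array(rnorm(h * w * Tn), c(h, w, Tn))
  out <- convgru_layer(x, gp)
  # naive reference: explicit convolution loops, step-by-step recurrence
  conv_naive <- function(img, wm, b, k = 3) {
    cin <- dim(img)[3]; cout <- ncol(wm); p <- (k - 1) / 2
    pad <- array(0, c(h + 2 * p, w + 2 * p, cin))
    pad[(p + 1):(p + h), (p + 1):(p + w), ] <- img
    res <- array(0, c(h, w, cout))
    for (co in 1:cout) for (i in 1:h) for (j in 1:w) {
      s <- 0
      for (ch in 1:cin) for (dw in 0:(k - 1)) for (dh in 0:(k - 1)) {
        s <- s + pad[i + dh, j + dw, ch] * wm[dh + dw * k + (ch - 1) * k * k + 1, co]
      }
      res[i, j, co] <- s + b[co]
    }
    res
  }
  sig <- function(z) 1 / (1 + exp(-z))
  hs <- array(0, c(h, w, hc))
  for (t in 1:Tn) {
    xt <- array(x[, , t], c(h, w, 1))
    z <- sig(conv_naive(xt, gp$Wxz, gp$bz) + conv_naive(hs, gp$Whz, rep(0, hc)))
    r <- sig(conv_naive(xt, gp$Wxr, gp$br) + conv_naive(hs, gp$Whr, rep(0, hc)))
    cand <- tanh(conv_naive(xt, gp$Wxh, gp$bh) +
                   conv_naive(r * hs, gp$Whh, rep(0, hc)))
    hs <- (1 - z) * hs + z * cand
  }
  expect_equal(array(out[, , 1, ], c(h, w, hc)), hs, tolerance = 1e-6)
  # T = 1 depends only on that frame and the zero initial state
  o1 <- convgru_layer(array(x[, , 1], c(h, w, 1)), gp)
  xt <- array(x[, , 1], c(h, w, 1))
  z1 <- sig(conv_naive(xt, gp$Wxz, gp$bz))
  c1 <- tanh(conv_naive(xt, gp$Wxh, gp$bh))
  expect_equal(array(o1[, , 1, ], c(h, w, hc)), z1 * c1, tolerance = 1e-6)
  # all-zero input with zero biases stays at the zero hidden state
  gp0 <- gp; gp0$bz <- gp0$br <- gp0$bh <- rep(0, hc)
  expect_true(all(convgru_layer(array(0, c(h, w, 3)), gp0) == 0))
})

test_that("the temporal variant trains end to end on frame stacks", {
  ds <- generate_singlescanner_imbalanced(
    cohort_spec(n_pd = 6, n_control = 4, slices_per_subject = 1, volumes = 4,
                size = c(16, 16), seed = 41))
  ds <- split_subjects(ds, seed = 41)
  arch <- dc_architecture("convgru_dccnn", input_shape = c(4, 16, 16),
                          conv_filters = c(4), fc_sizes = c(8, 6),
                          gru_hidden = 2, taps = c("fc1", "fc2"))
  fit <- dccnn(ds, arch, plain_objective(),
               dccnn_control(batch_size = 8, epochs = 1, seed = 2,
                             lr_policy = "step_decay", optimizer = "adam"))
  expect_s3_class(fit, "dccnn")
  expect_true(all(is.finite(fit$history$loss)))
  ts <- dccnn:::get_timeseries(ds)
  p <- predict(fit, ts$series[, , , 1:3, drop = FALSE], type = "prob")
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3))
})
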