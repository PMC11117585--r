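test_that("weighted cross-entropy matches closed forms and validates input", {
  p2 <- matrix(c(0.5, 0.5), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(weighted_cross_entropy("a", p2), log(2))
  perfect <- matrix(c(1 - 1e-9, 1e-9), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(weighted_cross_entropy("a", perfect), 1e-6)
  # uniform weights equal the unweighted value; weights scale per class
  set.seed(2)
  pm <- matrix(runif(20), 10); pm <- pm / rowSums(pm)
  colnames(pm) <- c("a", "b")
  y <- sample(c("a", "b"), 10, TRUE)
  expect_equal(weighted_cross_entropy(y, pm, c(a = 1, b = 1)),
               weighted_cross_entropy(y, pm))
  expect_error(weighted_cross_entropy(c("a", "z"), pm[1:2, ]), "outside")
  bad <- pm; bad[1, ] <- c(0.7, 0.7)
  expect_error(weighted_cross_entropy(y, bad), "sum to 1")
})

test_that("l2 penalty sums squared weights, excluding biases and norm layers", {
  arch <- tiny_arch()
  net <- build_model(arch, seed = 1)
  manual <- 0
  for (ly in net$layers) if (ly$type %in% c("conv", "dense")) manual <- manual + sum(ly$W^2)
  expect_equal(l2_penalty(net), manual)
  # zeroing all weights gives 0 even with nonzero biases / BN params
  for (i in seq_along(net$layers)) {
    if (net$layers[[i]]$type %in% c("conv", "dense")) {
      net$layers[[i]]$W[] <- 0
      net$layers[[i]]$b[] <- 3
    }
    if (net$layers[[i]]$type == "bnorm") net$layers[[i]]$gamma[] <- 2
  }
  expect_equal(l2_penalty(net), 0)
  # single weight 3 -> 9; two weights (1, 2) -> 5
  net$layers[[1]]$W[1] <- 3
  expect_equal(l2_penalty(net), 9)
  net$layers[[1]]$W[1:2] <- c(1, 2)
  expect_equal(l2_penalty(net), 5)
})

test_that("class-bias objective decomposes into its three terms", {
  ds <- tiny_imbalanced(seed = 31)
  arch <- tiny_arch()
  fit <- dccnn(ds, arch, plain_objective(), fast_control(epochs = 1))
  idx <- which(ds$manifest$split == "train")[1:10]
  img <- ds$images[, , idx]
  labels <- ds$manifest$class[idx]
  b <- dummy_class_bias(labels, seed = 3)
  spec <- class_bias_objective(lambda = 0.4, class_weights = c(PD = 1, control = 1),
                               l2 = 0.01)
  br <- evaluate_objective(fit, img, labels, spec, bias = b)
  # hand-assemble the three terms independently
  probs <- predict(fit, img, type = "prob")
  f <- extract_features(fit, img)
  expect_equal(br$ce, weighted_cross_entropy(labels, probs, spec$class_weights))
  expect_equal(br$dc2, distance_correlation_sq(b, f))
  expect_equal(br$l2, 0.01 * l2_penalty(fit))
  expect_equal(br$total, br$ce + 0.4 * br$dc2 + br$l2, tolerance = 1e-9)
  # lambda = 0 reduces exactly to weighted CE + L2
  br0 <- evaluate_objective(fit, img, labels,
                            class_bias_objective(lambda = 0,
                                                 class_weights = spec$class_weights,
                                                 l2 = 0.01), bias = b)
  expect_equal(br0$total, br$ce + br$l2)
  # F proportional to B gives a DC term of exactly lambda * 1
  brf <- dccnn:::breakdown_from(probs, 2 * b + 1, labels, spec, b, NULL,
                                l2_value = 0)
  expect_equal(brf$dc_term, 0.4 * 1.0)
  # batch below the penalty minimum skips the DC term and flags it
  brs <- evaluate_objective(fit, ds$images[, , idx[1:4]], labels[1:4], spec,
                            bias = b[1:4, , drop = FALSE], min_dc_batch = 8)
  expect_true(brs$dc_skipped)
  expect_equal(brs$dc_term, 0)
})

test_that("scanner objective restricts decorrelation to weighted controls", {
  ds <- tiny_multiscanner(seed = 32)
  arch <- tiny_arch()
  fit <- dccnn(ds, arch, plain_objective(), fast_control(epochs = 1))
  # a batch with both classes and >= 8 controls spanning both scanners
  trn <- which(ds$manifest$split == "train")
  idx <- c(utils::head(trn[ds$manifest$class[trn] == "PD"], 12),
           utils::head(trn[ds$manifest$class[trn] == "control"], 12))
  img <- ds$images[, , idx]
  labels <- ds$manifest$class[idx]
  scanner <- ds$manifest$scanner_id[idx]
  b <- voxel_size_bias(ds$manifest[idx, ])
  spec <- scanner_objective(lambda1 = 0.5, lambda2 = 2, l2 = 0.005)
  br <- evaluate_objective(fit, img, labels, spec, bias = b, scanner_id = scanner)
  ctrl <- labels == "control"
  probs <- predict(fit, img, type = "prob")
  f <- extract_features(fit, img)
  expect_equal(br$ce, 0.5 * weighted_cross_entropy(labels, probs))
  # uniform weights reduce the DC term to the unweighted control-only dCor
  expect_equal(br$dc2,
               weighted_distance_correlation_sq(b[ctrl, ], f[ctrl, ],
                                                rep(1, sum(ctrl))))
  # scanner-coded features against scanner-derived B give DC exactly 1
  fs <- cbind(as.integer(factor(scanner)))
  brf <- dccnn:::breakdown_from(probs, fs, labels, spec, b, scanner, l2_value = 0)
  expect_equal(brf$dc_term, 2 * 1.0, tolerance = 1e-9)
  # a batch with no controls only carries CE + L2, with the skip flagged
  pd <- which(labels == "PD")
  brn <- evaluate_objective(fit, ds$images[, , idx[pd]], labels[pd], spec,
                            bias = b[pd, , drop = FALSE], scanner_id = scanner[pd])
  expect_true(brn$dc_skipped)
  expect_equal(brn$total, brn$ce + brn$l2)
  # missing scanner id on a control sample is an error
  sc2 <- scanner; sc2[which(ctrl)[1]] <- NA
  expect_error(evaluate_objective(fit, img, labels, spec, bias = b,
                                  scanner_id = sc2), "missing scanner id")
})

test_that("increasing lambda strictly increases the loss when DC^2 > 0", {
  ds <- tiny_imbalanced(seed = 33)
  fit <- dccnn(ds, tiny_arch(), plain_objective(), fast_control(epochs = 1))
  idx <- which(ds$manifest$split == "train")[1:16]
  img <- ds$images[, , idx]; labels <- ds$manifest$class[idx]
  b <- dummy_class_bias(labels, seed = 5)
  vals <- vapply(c(0, 0.5, 1, 2), function(l) {
    evaluate_objective(fit, img, labels,
                       class_bias_objective(lambda = l), bias = b)$total
  }, 0)
  expect_gt(evaluate_objective(fit, img, labels, class_bias_objective(1),
                               bias = b)$dc2, 0)
  expect_true(all(diff(vals) > 0))
})
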