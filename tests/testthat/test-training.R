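test_that("exponential cyclical schedule hits the declared anchor points", {
  expect_equal(exp_cyclical_lr(0, 1e-4, 1e-2, 50, 1), 1e-4)          # cycle start
  expect_equal(exp_cyclical_lr(50, 1e-4, 1e-2, 50, 1), 1e-2)         # cycle peak
  expect_equal(exp_cyclical_lr(100, 1e-4, 1e-2, 50, 1), 1e-4)        # cycle end
  # gamma < 1: each successive peak is strictly lower
  peaks <- exp_cyclical_lr(c(50, 150, 250), 1e-4, 1e-2, 50, 0.995)
  expect_true(all(diff(peaks) < 0))
  expect_error(exp_cyclical_lr(0, 1e-2, 1e-4, 50), "base_lr < max_lr")
  expect_error(exp_cyclical_lr(0, 1e-4, 1e-2, 50, gamma = 1.5), "gamma")
})

test_that("training is fully deterministic per seed", {
  ds <- tiny_imbalanced(seed = 23)
  arch <- tiny_arch()
  f1 <- dccnn(ds, arch, class_bias_objective(lambda = 0.5), fast_control(seed = 9))
  f2 <- dccnn(ds, arch, class_bias_objective(lambda = 0.5), fast_control(seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1), coef(f2))
  f3 <- dccnn(ds, arch, class_bias_objective(lambda = 0.5), fast_control(seed = 10))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("a zero decorrelation weight reproduces the baseline bitwise", {
  ds <- tiny_imbalanced(seed = 24)
  arch <- tiny_arch()
  ctl <- fast_control(seed = 5)
  base <- dccnn(ds, arch, plain_objective(l2 = 1e-4), ctl)
  # class-bias objective, lambda = 0, uniform class weights == plain CE model
  eq2 <- dccnn(ds, arch, class_bias_objective(lambda = 0,
                                              class_weights = c(PD = 1, control = 1),
                                              l2 = 1e-4), ctl)
  expect_identical(base$history$loss, eq2$history$loss)
  expect_identical(coef(base), coef(eq2))
  # scanner objective with lambda1 = 1, lambda2 = 0 == plain CE model
  dm <- tiny_multiscanner(seed = 25)
  base2 <- dccnn(dm, arch, plain_objective(l2 = 0.005), fast_control(seed = 6))
  eq3 <- dccnn(dm, arch, scanner_objective(lambda1 = 1, lambda2 = 0, l2 = 0.005),
               fast_control(seed = 6))
  expect_identical(base2$history$loss, eq3$history$loss)
  expect_identical(coef(base2), coef(eq3))
})

test_that("the logged DC term matches an offline recomputation", {
  ds <- tiny_multiscanner(seed = 26)
  arch <- tiny_arch()
  # freeze a fitted model, replay one batch through evaluate_objective
  obj <- scanner_objective(lambda1 = 0.5, lambda2 = 2, l2 = 0.005)
  fit <- dccnn(ds, arch, obj, fast_control(seed = 7, epochs = 1, batch_size = 64))
  h <- fit$history
  expect_true(any(is.finite(h$dc2)))
  ok <- is.finite(h$dc2)
  expect_equal(h$dc_term[ok], 2 * h$dc2[ok], tolerance = 1e-9)
  expect_true(all(abs(h$loss - (h$ce + h$dc_term + h$l2)) < 1e-9))
})

test_that("subject-level split integrity is preserved through resampling", {
  ds <- tiny_imbalanced(seed = 27)
  dsr <- random_oversample(ds, seed = 1)
  tab <- table(dsr$manifest$subject_id, dsr$manifest$split)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("replicated runs differ by seed and aggregate with a t interval", {
  ds <- tiny_imbalanced(seed = 28)
  runs <- dccnn_replicate(ds, tiny_arch(), plain_objective(),
                          fast_control(seed = 30, epochs = 1), n_runs = 3)
  expect_length(runs, 3)
  seeds <- vapply(runs, function(f) f$control$seed, 0L)
  expect_equal(seeds, c(30L, 31L, 32L))
  bas <- vapply(runs, function(f) {
    evaluate_model(f, ds)$slice$balanced_accuracy
  }, 0)
  ri <- run_interval(bas)
  expect_true(is.finite(ri$mean))
  expect_gte(ri$upper, ri$lower)
})

test_that("NaN losses abort with a diagnostic naming the iteration", {
  ds <- tiny_imbalanced(seed = 29)
  tr <- which(ds$manifest$split == "train")
  ds$images[1, 1, tr[1]] <- NaN              # corrupt one training pixel
  expect_error(dccnn(ds, tiny_arch(), plain_objective(),
                     fast_control(seed = 2, epochs = 1, batch_size = 128)),
               "non-finite loss at iteration")
})

test_that("fit methods expose the usual modelling surface", {
  ds <- tiny_imbalanced(seed = 35)
  fit <- dccnn(ds, tiny_arch(), class_bias_objective(lambda = 0.3),
               fast_control(seed = 3, epochs = 1))
  expect_output(print(fit), "Decorrelated CNN fit")
  expect_output(summary(fit), "DC\\^2")
  p <- predict(fit, ds, type = "prob")
  expect_equal(ncol(p), 2)
  cl <- predict(fit, ds, type = "class")
  expect_s3_class(cl, "factor")
  f <- predict(fit, ds, type = "feature", taps = "softmax")
  expect_equal(ncol(f), 2)
  r <- residuals(fit, ds, positive = "PD")
  expect_true(all(abs(r) <= 1))
  co <- coef(fit)
  expect_true(any(grepl("conv", names(co))))
  tf <- file.path(withr::local_tempdir(), "p.pdf")
  grDevices::pdf(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
})

test_that("scanner decorrelation trains with FE-feature and temporal-std bias variables", {
  # FE-feature bias: a scanner classifier's frozen conv features feed B
  dm <- tiny_multiscanner(seed = 37)
  fe <- dccnn(dm, tiny_arch(taps = "conv2"), plain_objective(),
              fast_control(seed = 4, epochs = 1))
  fit <- dccnn(dm, tiny_arch(),
               scanner_objective(lambda1 = 0.5, lambda2 = 1, bias = "fe_features"),
               fast_control(seed = 5, epochs = 1), fe_model = fe)
  expect_true(all(is.finite(fit$history$loss)))
  expect_error(dccnn(dm, tiny_arch(),
                     scanner_objective(bias = "fe_features"),
                     fast_control(seed = 5, epochs = 1)), "fe_model")
  # temporal-std bias: only defined for the temporal architecture
  expect_error(dccnn(dm, tiny_arch(),
                     scanner_objective(bias = "temporal_std"),
                     fast_control(seed = 5, epochs = 1)), "temporal")
  dt <- generate_multiscanner(cohort_spec(n_pd = 4, n_control = 6,
                                          slices_per_subject = 1, volumes = 3,
                                          size = c(16, 16), seed = 38),
                              control_ratio = c(1, 1))
  dt <- split_subjects(dt, seed = 38)
  archt <- dc_architecture("convgru_dccnn", input_shape = c(3, 16, 16),
                           conv_filters = c(4), fc_sizes = c(8, 6),
                           gru_hidden = 2, taps = c("fc1", "fc2"))
  fitt <- dccnn(dt, archt,
                scanner_objective(lambda1 = 0.5, lambda2 = 1,
                                  bias = "temporal_std"),
                dccnn_control(batch_size = 8, epochs = 1, seed = 6,
                              optimizer = "adam", lr_policy = "step_decay",
                              min_dc_batch = 2))
  expect_true(all(is.finite(fitt$history$loss)))
})
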