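# Study-scale experiment drivers.
#
# These functions run the two synthetic studies end to end — data generation,
# training of the method and its baselines over several seeded replicates,
# and evaluation — and are what the acceptance script and the heavier tests
# call. Each replicate r uses its own derived data seed and init seed, so the
# reported means aggregate over both sampling and initialization noise.
# Problem sizes are desk-scale choices documented in the methods vignette.

desk_arch <- function(taps = c("fc1", "fc2", "softmax")) {
  dc_architecture("custom", input_shape = c(66, 66),
                  conv_filters = c(6, 12, 12), fc_sizes = c(32, 16),
                  dropout = 0.2, taps = taps)
}

desk_control <- function(seed, epochs = 8L) {
  dccnn_control(batch_size = 64L, epochs = epochs, base_lr = 1e-4,
                max_lr = 3e-3, half_cycle = 30L, gamma = 0.999, seed = seed,
                dc_warmup = 0.4)
}

dc_trend <- function(fit) {
  d <- fit$history$dc2[is.finite(fit$history$dc2)]
  if (!length(d)) return(c(first = NA_real_, last = NA_real_))
  k <- max(1L, length(d) %/% 10L)
  c(first = mean(d[seq_len(k)]), last = mean(d[(length(d) - k + 1L):length(d)]))
}

#' Class-bias mitigation study on synthetic 9:1 fixtures
#'
#' Replicates the single-scanner imbalanced experiment with three methods: a
#' plain CNN on the imbalanced data (expected to collapse toward the majority
#' class), random oversampling (ROS), and the fusion method (ROS + weighted
#' cross-entropy + decorrelation against the dummy class-bias variable;
#' after ROS the inverse-frequency class weights are uniform). Each
#' replicate regenerates the cohort with a derived seed and retrains every
#' method.
#'
#' @param seed Master seed.
#' @param n_runs Number of replicates, default 3.
#' @param n_pd,n_control Subject counts (default 108/12, the 9:1 design).
#' @param epochs Training epochs per run.
#' @param lambda Decorrelation weight of the fusion objective.
#' @param verbose Print per-run metric lines.
#' @return List with \code{runs} (per-replicate metric lists) and
#'   \code{summary} (per-method means of sensitivity, specificity, balanced
#'   accuracy; the fusion DC^2 trend; subject-level fusion metrics).
#' @export
experiment_class_bias <- function(seed = 1L, n_runs = 3L, n_pd = 108L,
                                  n_control = 12L, epochs = 8L, lambda = 1,
                                  verbose = FALSE) {
  methods <- c("baseline", "ros", "fusion")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    dseed <- derive_seed(seed, 10L + r)
    iseed <- derive_seed(seed, 50L + r)
    ds <- generate_singlescanner_imbalanced(
      cohort_spec(n_pd = n_pd, n_control = n_control, seed = dseed))
    ds <- split_subjects(ds, seed = dseed)
    arch <- desk_arch()
    ctl <- desk_control(iseed, epochs)
    dsr <- random_oversample(ds, seed = dseed + 1L)
    fits <- list(
      baseline = dccnn(ds, arch, plain_objective(), ctl),
      ros = dccnn(dsr, arch, plain_objective(), ctl),
      fusion = dccnn(dsr, arch, class_bias_objective(lambda = lambda), ctl))
    out <- list()
    for (nm in methods) {
      ev <- evaluate_model(fits[[nm]], ds)
      out[[nm]] <- list(slice = ev$slice, subject = ev$subject)
      if (verbose) {
        message(sprintf("run %d %-8s sens %5.1f spec %5.1f BA %5.1f", r, nm,
                        ev$slice$sensitivity, ev$slice$specificity,
                        ev$slice$balanced_accuracy))
      }
    }
    out$fusion$dc_trend <- dc_trend(fits$fusion)
    runs[[r]] <- out
  }
  summ <- list()
  for (nm in methods) {
    summ[[nm]] <- list(
      sensitivity = mean(vapply(runs, function(x) x[[nm]]$slice$sensitivity, 0)),
      specificity = mean(vapply(runs, function(x) x[[nm]]$slice$specificity, 0)),
      balanced_accuracy = run_interval(
        vapply(runs, function(x) x[[nm]]$slice$balanced_accuracy, 0)),
      subject_balanced_accuracy = mean(
        vapply(runs, function(x) x[[nm]]$subject$balanced_accuracy, 0)))
  }
  summ$fusion$dc_first <- mean(vapply(runs, function(x) x$fusion$dc_trend["first"], 0))
  summ$fusion$dc_last <- mean(vapply(runs, function(x) x$fusion$dc_trend["last"], 0))
  list(runs = runs, summary = summ)
}

#' Scanner-bias mitigation study on synthetic multiscanner fixtures
#'
#' Replicates the two-scanner experiment in which PD subjects appear on one
#' scanner only and controls on both (1:9): a plain CNN baseline and the
#' scanner-decorrelated model (control-only weighted dCor against the
#' voxel-size bias variable). Each fitted model is audited with the linear
#' scanner probe on its frozen fully connected features of held-out control
#' slices. A scanner-null replicate (identical acquisition transforms)
#' calibrates the probe's chance band.
#'
#' @param seed Master seed.
#' @param n_runs Number of replicates, default 3.
#' @param n_pd,n_control Subject counts, default 40/60.
#' @param epochs Training epochs per run.
#' @param lambda1,lambda2 Trade-off weights of the scanner objective.
#' @param verbose Print per-run metric lines.
#' @return List with \code{runs} and \code{summary} (baseline/dccnn balanced
#'   accuracy and probe accuracy means, the probe drop, and the
#'   scanner-null probe accuracy with its binomial 95\% band).
#' @export
experiment_scanner_bias <- function(seed = 1L, n_runs = 3L, n_pd = 40L,
                                    n_control = 60L, epochs = 8L,
                                    lambda1 = 0.5, lambda2 = 12,
                                    verbose = FALSE) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    dseed <- derive_seed(seed, 20L + r)
    iseed <- derive_seed(seed, 70L + r)
    ds <- generate_multiscanner(
      cohort_spec(n_pd = n_pd, n_control = n_control, seed = dseed))
    ds <- split_subjects(ds, seed = dseed)
    arch <- desk_arch()
    ctl <- desk_control(iseed, epochs)
    base <- dccnn(ds, arch, plain_objective(l2 = 0.005), ctl)
    dcf <- dccnn(ds, arch,
                 scanner_objective(lambda1 = lambda1, lambda2 = lambda2,
                                   bias = "voxel_size"), ctl)
    out <- list(
      baseline = list(slice = evaluate_model(base, ds)$slice,
                      probe = probe_heldout_controls(base, ds, iseed)),
      dccnn = list(slice = evaluate_model(dcf, ds)$slice,
                   probe = probe_heldout_controls(dcf, ds, iseed),
                   dc_trend = dc_trend(dcf)))
    if (verbose) {
      message(sprintf(
        "run %d baseline BA %5.1f probe %5.1f | dccnn BA %5.1f probe %5.1f",
        r, out$baseline$slice$balanced_accuracy, out$baseline$probe,
        out$dccnn$slice$balanced_accuracy, out$dccnn$probe))
    }
    runs[[r]] <- out
  }
  # scanner-null calibration: identical image transforms, distinct metadata
  nseed <- derive_seed(seed, 99L)
  null_profiles <- list(
    ppmi = scanner_profile("ppmi_like"),
    nifd = scanner_profile("ppmi_like", slice_thickness_mm = 3.0,
                           pixel_spacing_mm = c(2.5, 2.5)))
  dsn <- generate_multiscanner(
    cohort_spec(n_pd = n_pd, n_control = n_control, seed = nseed),
    profiles = null_profiles)
  dsn <- split_subjects(dsn, seed = nseed)
  basen <- dccnn(dsn, desk_arch(), plain_objective(l2 = 0.005),
                 desk_control(derive_seed(seed, 98L), epochs))
  null_probe <- probe_heldout_controls(basen, dsn, nseed)
  nt <- attr(null_probe, "n_test") %||% 40L
  band <- 100 * 1.96 * sqrt(0.25 / nt)
  summ <- list(
    baseline_ba = mean(vapply(runs, function(x) x$baseline$slice$balanced_accuracy, 0)),
    baseline_probe = mean(vapply(runs, function(x) as.numeric(x$baseline$probe), 0)),
    dccnn_ba = mean(vapply(runs, function(x) x$dccnn$slice$balanced_accuracy, 0)),
    dccnn_probe = mean(vapply(runs, function(x) as.numeric(x$dccnn$probe), 0)),
    null_probe = as.numeric(null_probe), null_band = band)
  summ$probe_drop <- summ$baseline_probe - summ$dccnn_probe
  list(runs = runs, summary = summ)
}

# Scanner probe on the frozen FC features of held-out (val + test) controls.
probe_heldout_controls <- function(fit, ds, seed) {
  m <- ds$manifest
  idx <- which(m$split %in% c("val", "test") & m$class == "control")
  feats <- extract_features(fit, ds$images[, , idx, drop = FALSE],
                            taps = c("fc1", "fc2"))
  scanner_probe_accuracy(feats, m$scanner_id[idx], m$subject_id[idx],
                         seed = seed)
}
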