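test_that("confusion metrics match hand-counted tables and printed rows", {
  # TP=3 FN=1 TN=2 FP=2
  yt <- c(rep("PD", 4), rep("control", 4))
  yp <- c("PD", "PD", "PD", "control", "PD", "PD", "control", "control")
  m <- confusion_metrics(yt, yp)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 50)
  expect_equal(m$precision, 60)
  expect_equal(m$balanced_accuracy, 62.5)
  # BA identity holds on every report
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
  # majority collapse on a 9:1 set: sens 100, spec 0, BA 50
  yt2 <- c(rep("PD", 9), "control")
  m2 <- confusion_metrics(yt2, rep("PD", 10))
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)
  expect_equal(m2$balanced_accuracy, 50)
  # undefined metrics are NA, not 0
  m3 <- confusion_metrics(rep("PD", 5), rep("PD", 5))
  expect_true(is.na(m3$specificity))
})

test_that("max-wins voting is a pure, order-invariant function with the declared tie-break", {
  pred <- data.frame(
    subject_id = rep(c("s1", "s2"), c(25, 20)),
    pred_class = c(rep("PD", 13), rep("control", 12),
                   rep("PD", 10), rep("control", 10)),
    prob_positive = c(rep(0.6, 25), rep(0.61, 10), rep(0.59, 10)),
    class = rep(c("PD", "control"), c(25, 20)))
  v <- max_wins_vote(pred)
  expect_equal(v$pred_class[v$subject_id == "s1"], "PD")      # 13 of 25 votes
  expect_equal(v$pred_class[v$subject_id == "s2"], "PD")      # tie, mean prob 0.6
  # tie the other way
  pred2 <- pred[pred$subject_id == "s2", ]
  pred2$prob_positive <- 1 - pred2$prob_positive
  expect_equal(max_wins_vote(pred2)$pred_class, "control")
  # permutation invariance
  set.seed(1)
  vp <- max_wins_vote(pred[sample(nrow(pred)), ])
  expect_identical(v[order(v$subject_id), ], vp[order(vp$subject_id), ])
  expect_error(max_wins_vote(pred[, 1:2]), "lacks column")
})

test_that("scanner probe separates coded features and is at chance on permuted ones", {
  set.seed(7)
  n <- 120
  scanner <- rep(c("A", "B"), each = n / 2)
  subject <- paste0("s", rep(1:40, each = 3))
  onehot <- cbind(as.integer(scanner == "A"), as.integer(scanner == "B"),
                  matrix(rnorm(n * 4), n))
  expect_equal(scanner_probe_accuracy(onehot, scanner, subject, seed = 1),
               100, ignore_attr = TRUE)
  # permuted labels: accuracy within the binomial noise band around 50%
  accs <- vapply(1:5, function(s) {
    perm <- sample(scanner)
    as.numeric(scanner_probe_accuracy(matrix(rnorm(n * 6), n), perm,
                                      subject, seed = s))
  }, 0)
  expect_lt(abs(mean(accs) - 50), 15)
  expect_message(scanner_probe_accuracy(onehot, rep("A", n), subject),
                 "one scanner")
})

test_that("per-dataset error rates restrict accuracy to each scanner", {
  yt <- c("PD", "PD", "control", "control", "PD", "control", "control", "PD")
  yp <- c("PD", "control", "control", "control", "PD", "PD", "control", "PD")
  dsid <- rep(c("NIFD", "PPMI"), each = 4)
  er <- per_dataset_error_rate(yt, yp, dsid)
  expect_equal(unname(er["NIFD"]), 0.25)
  expect_equal(unname(er["PPMI"]), 0.25)
  expect_equal(unname(per_dataset_error_rate(yt, yt, dsid)), c(0, 0))
})

test_that("ROC table covers the standard sweep cases", {
  yt <- c(rep("PD", 5), rep("control", 5))
  r1 <- roc_table(yt, c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(attr(r1, "auc"), 1.0)
  r0 <- roc_table(yt, c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(attr(r0, "auc"), 0.0)
  expect_warning(rc <- roc_table(yt, rep(0.5, 10)), "constant")
  expect_equal(attr(rc, "auc"), 0.5)
  set.seed(3)
  ybig <- sample(c("PD", "control"), 4000, TRUE)
  rr <- roc_table(ybig, runif(4000))
  expect_equal(attr(rr, "auc"), 0.5, tolerance = 0.05)
  # cross-check the trapezoid AUC against an established implementation
  set.seed(4)
  sc <- runif(60); yy <- ifelse(runif(60) < plogis(4 * sc - 2), "PD", "control")
  if (requireNamespace("pROC", quietly = TRUE) &&
      length(unique(yy)) == 2L) {
    ref <- as.numeric(pROC::auc(pROC::roc(response = factor(yy, c("control", "PD")),
                                          predictor = sc, quiet = TRUE)))
    expect_equal(attr(roc_table(yy, sc), "auc"), ref, tolerance = 1e-9)
  }
})

test_that("t-SNE export is seeded and its silhouette tracks cluster structure", {
  set.seed(11)
  well <- rbind(matrix(rnorm(30 * 4, 0), 30), matrix(rnorm(30 * 4, 8), 30))
  scanner <- rep(c("A", "B"), each = 30)
  e1 <- embedding_export(well, labels = rep("control", 60), scanner_id = scanner,
                         seed = 5, perplexity = 8)
  expect_gt(attr(e1, "scanner_silhouette"), 0.5)
  e1b <- embedding_export(well, rep("control", 60), scanner, seed = 5,
                          perplexity = 8)
  expect_identical(e1, e1b)
  # identically distributed scanners: silhouette near zero
  null <- matrix(rnorm(60 * 4), 60)
  e0 <- embedding_export(null, rep("control", 60), scanner, seed = 6,
                         perplexity = 8)
  expect_lt(abs(attr(e0, "scanner_silhouette")), 0.15)
  expect_error(embedding_export(well[1:8, ], rep("c", 8), rep("A", 8)),
               "at least 10")
  expect_error(embedding_export(well[1:20, ], rep("c", 20), scanner[1:20],
                                perplexity = 10), "perplexity")
})

test_that("run intervals use the t quantile closed form", {
  r <- run_interval(c(1, 1, 1))
  expect_equal(r$mean, 1); expect_equal(r$half_width, 0)
  r2 <- run_interval(c(0, 1, 2))
  expect_equal(r2$half_width, stats::qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(r2$half_width, 4.303 * 1 / sqrt(3), tolerance = 1e-4)
  r3 <- run_interval(c(3, 5))
  expect_equal(r3$half_width, 12.706 * stats::sd(c(3, 5)) / sqrt(2),
               tolerance = 1e-3)
  r1 <- run_interval(7)
  expect_equal(r1$mean, 7); expect_true(is.na(r1$half_width))
})
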