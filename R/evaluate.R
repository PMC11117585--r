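# Metrics, subject-level aggregation, and bias audits.

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, precision, balanced accuracy, accuracy and F1
#' (all in percent) for a two-class problem. A metric whose denominator is
#' empty (e.g. specificity when no true negatives exist in \code{y_true}) is
#' reported as \code{NA}, not 0.
#'
#' @param y_true,y_pred Label vectors.
#' @param positive The positive class (the disease class).
#' @return List with fields \code{sensitivity, specificity, precision,
#'   balanced_accuracy, accuracy, f1} (percent) and the raw counts
#'   \code{tp, fp, tn, fn}.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = "PD") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  ba <- mean(c(sens, spec))
  acc <- 100 * (tp + tn) / length(y_true)
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec,
       balanced_accuracy = ba, accuracy = acc, f1 = f1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Max-wins subject-level voting
#'
#' Aggregates slice-level predictions to one label per subject: the class
#' with the most slice votes wins; ties break deterministically toward the
#' class with the higher mean predicted positive-class probability. A pure
#' function of the prediction table — permuting its rows cannot change the
#' outcome.
#'
#' @param pred Data frame with columns \code{subject_id}, \code{pred_class},
#'   \code{prob_positive}, and optionally \code{class} (the true label,
#'   carried through).
#' @param positive The positive class used for the tie-break.
#' @return Data frame with one row per subject: \code{subject_id},
#'   \code{pred_class}, \code{votes}, \code{n_slices}, and \code{class} if
#'   present in the input.
#' @export
max_wins_vote <- function(pred, positive = "PD") {
  need <- c("subject_id", "pred_class", "prob_positive")
  miss <- setdiff(need, names(pred))
  if (length(miss)) stop("prediction table lacks column(s): ",
                         paste(miss, collapse = ", "))
  groups <- split(seq_len(nrow(pred)), pred$subject_id)
  groups <- groups[sort(names(groups), method = "radix")]
  rows <- lapply(names(groups), function(sid) {
    g <- groups[[sid]]
    if (!length(g)) stop("subject with zero slices: ", sid)
    tab <- sort(table(pred$pred_class[g]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) == 1L) top else {
      mp <- mean(pred$prob_positive[g])
      if (mp >= 0.5) positive else setdiff(top, positive)[1]
    }
    out <- data.frame(subject_id = sid, pred_class = lab,
                      votes = as.integer(max(tab)), n_slices = length(g),
                      stringsAsFactors = FALSE)
    if ("class" %in% names(pred)) out$class <- pred$class[g[1]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Scanner-probe accuracy of learned features
#'
#' The bias audit: a ridge-regularized linear probe is trained on a
#' subject-grouped 70/30 split of held-out control features to predict the
#' scanner, and its held-out balanced accuracy (percent) is returned. The
#' probe is class-weighted and the metric is balanced, because control
#' cohorts are heavily scanner-imbalanced (1:9 by design) and a raw accuracy
#' would sit at the majority prior instead of 50 under the null. High values
#' mean the features still carry scanner information; features truly
#' invariant to the scanner probe near 50%.
#'
#' @param features Feature matrix (rows = samples), from the frozen model.
#' @param scanner_id Per-sample scanner labels (>= 2 scanners required).
#' @param subject_id Per-sample subject ids for the grouped split.
#' @param seed Split seed.
#' @param train_frac Fraction of subjects used to fit the probe.
#' @return Accuracy in percent, with attribute \code{n_test}. \code{NA} (with
#'   a message) if only one scanner is present.
#' @export
scanner_probe_accuracy <- function(features, scanner_id, subject_id,
                                   seed = 1L, train_frac = 0.7) {
  scanner_id <- as.character(scanner_id)
  if (length(unique(scanner_id)) < 2L) {
    message("scanner probe undefined: only one scanner present")
    return(NA_real_)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  subj <- unique(data.frame(subject_id = subject_id, scanner_id = scanner_id))
  by_scanner <- split(subj$subject_id, subj$scanner_id)
  by_scanner <- by_scanner[sort(names(by_scanner), method = "radix")]
  tr_subj <- unlist(lapply(by_scanner, function(s) {
    sample(s, max(1L, round(train_frac * length(s))))
  }))
  tr <- subject_id %in% tr_subj
  if (length(unique(scanner_id[tr])) < 2L || length(unique(scanner_id[!tr])) < 2L) {
    message("scanner probe undefined: a split lost a scanner")
    return(NA_real_)
  }
  ytr <- factor(scanner_id[tr])
  wts <- as.numeric(inverse_frequency_weights(ytr)[as.character(ytr)])
  fit <- glmnet::glmnet(features[tr, , drop = FALSE], ytr,
                        family = "binomial", weights = wts,
                        alpha = 0, lambda = 1e-2, standardize = TRUE)
  pr <- as.vector(stats::predict(fit, features[!tr, , drop = FALSE],
                                 type = "class"))
  truth <- scanner_id[!tr]
  acc <- mean(vapply(sort(unique(truth), method = "radix"), function(s) {
    100 * mean(pr[truth == s] == s)
  }, 0))
  attr(acc, "n_test") <- sum(!tr)
  acc
}

#' Per-dataset (per-scanner) error rate
#'
#' \eqn{1 - } accuracy restricted to each dataset's samples. A dataset with
#' no samples is omitted with a message.
#'
#' @param y_true,y_pred Label vectors.
#' @param dataset_id Per-sample dataset/scanner ids.
#' @return Named numeric vector of error rates in \eqn{[0, 1]}.
#' @export
per_dataset_error_rate <- function(y_true, y_pred, dataset_id) {
  ids <- unique(as.character(dataset_id))
  out <- vapply(ids, function(d) {
    sel <- dataset_id == d
    if (!any(sel)) return(NA_real_)
    mean(y_true[sel] != y_pred[sel])
  }, 0)
  if (anyNA(out)) message("dataset(s) without samples omitted")
  out[!is.na(out)]
}

#' ROC table and AUC
#'
#' Standard threshold sweep over the positive-class scores; AUC by the
#' trapezoid rule. Constant scores yield AUC 0.5 with a degeneracy warning.
#'
#' @param y_true Label vector.
#' @param scores Positive-class scores (finite).
#' @param positive The positive class.
#' @return Data frame of (fpr, tpr) pairs with attribute \code{auc}.
#' @export
roc_table <- function(y_true, scores, positive = "PD") {
  if (any(!is.finite(scores))) stop("scores must be finite")
  y <- as.integer(as.character(y_true) == positive)
  if (length(unique(scores)) == 1L) {
    warning("constant scores: ROC degenerate, AUC 0.5")
    out <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
    attr(out, "auc") <- 0.5
    return(out)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(y == 1L); N <- sum(y == 0L)
  tpr <- vapply(th, function(t) sum(scores >= t & y == 1L) / P, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & y == 0L) / N, 0)
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "auc") <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out
}

#' 2-D t-SNE embedding export
#'
#' Seeded exact (O(n^2)) t-distributed stochastic neighbor embedding of a
#' feature matrix, returned as a tidy table for plotting, together with a
#' quantitative companion: the mean silhouette width of the scanner grouping
#' on the embedding (near 0 when scanners are mixed, large when they
#' separate).
#'
#' @param features Feature matrix, n >= 10 rows.
#' @param labels,scanner_id Per-sample class and scanner annotations.
#' @param seed Seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; must satisfy \code{n > 3 * perplexity}.
#' @param max_iter Gradient-descent iterations, default 300.
#' @return Data frame (x, y, class, scanner) with attribute
#'   \code{scanner_silhouette}.
#' @export
embedding_export <- function(features, labels, scanner_id, seed = 1L,
                             perplexity = 10, max_iter = 300L) {
  n <- nrow(features)
  if (n < 10L) stop("need at least 10 samples to embed")
  if (n <= 3 * perplexity) {
    stop("too few samples for perplexity ", perplexity,
         "; reduce perplexity below n/3")
  }
  emb <- tsne_exact(as.matrix(features), perplexity = perplexity,
                    max_iter = max_iter, seed = seed)
  out <- data.frame(x = emb[, 1], y = emb[, 2],
                    class = as.character(labels),
                    scanner = as.character(scanner_id),
                    stringsAsFactors = FALSE)
  sil <- if (length(unique(out$scanner)) >= 2L) {
    sw <- cluster::silhouette(as.integer(factor(out$scanner)),
                              stats::dist(emb))
    mean(sw[, "sil_width"])
  } else NA_real_
  attr(out, "scanner_silhouette") <- sil
  out
}

# Exact t-SNE: perplexity-calibrated Gaussian affinities, early exaggeration,
# momentum gradient descent. Small-n implementation.
tsne_exact <- function(x, perplexity = 10, max_iter = 300L, seed = 1L) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p <- p * 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- Y * 0; gains <- Y * 0 + 1
  momentum <- 0.5
  for (it in seq_len(max_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    dY <- momentum * dY - 200 * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 100) momentum <- 0.8
  }
  Y
}

#' Evaluate a fitted model on a dataset split
#'
#' Runs the model on the requested split and assembles the full evaluation
#' report: slice-level confusion metrics, subject-level metrics after
#' max-wins voting, per-scanner error rates (subject level), and the slice
#' prediction table the subject metrics are derived from.
#'
#' @param fit A fitted [dccnn()].
#' @param ds The \code{slice_dataset} (with split column).
#' @param split Which split to evaluate, default \code{"test"}.
#' @param positive Positive class, default \code{"PD"}.
#' @return List with \code{slice}, \code{subject} (metric lists),
#'   \code{per_scanner_error}, \code{predictions} (slice table),
#'   \code{subject_predictions}.
#' @export
evaluate_model <- function(fit, ds, split = "test", positive = "PD") {
  man <- if (fit$arch$temporal) get_timeseries(ds)$manifest else ds$manifest
  idx <- which(man$split == split)
  if (!length(idx)) stop("no samples in split '", split, "'")
  x <- if (fit$arch$temporal) {
    get_timeseries(ds)$series[, , , idx, drop = FALSE]
  } else ds$images[, , idx, drop = FALSE]
  p <- net_predict(fit$net, x)
  colnames(p) <- fit$classes
  pred <- data.frame(subject_id = man$subject_id[idx],
                     scanner_id = man$scanner_id[idx],
                     class = man$class[idx],
                     pred_class = fit$classes[max.col(p, ties.method = "first")],
                     prob_positive = if (positive %in% colnames(p))
                       p[, positive] else p[, ncol(p)],
                     stringsAsFactors = FALSE)
  sl <- confusion_metrics(pred$class, pred$pred_class, positive)
  sv <- max_wins_vote(pred, positive)
  sj <- confusion_metrics(sv$class, sv$pred_class, positive)
  subj_scanner <- man$scanner_id[idx][match(sv$subject_id, man$subject_id[idx])]
  pse <- per_dataset_error_rate(sv$class, sv$pred_class, subj_scanner)
  list(slice = sl, subject = sj, per_scanner_error = pse,
       predictions = pred, subject_predictions = sv)
}
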