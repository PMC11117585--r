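# Seeded training of (decorrelated) CNNs.
#
# `dccnn()` is the fitting function: it takes a slice dataset with
# subject-grouped splits, an architecture, an objective, and a training
# control, and returns a classed fit with the full per-iteration loss
# breakdown (including the evaluated DC^2) in `$history`.

#' Training control parameters
#'
#' @param optimizer \code{"rmsprop"} or \code{"adam"}.
#' @param batch_size Minibatch size, default 128 (desk scale; larger batches
#'   stabilize the decorrelation estimate).
#' @param epochs Training epochs, default 10.
#' @param lr_policy \code{"exp_cyclical"} (triangular cycle between
#'   \code{base_lr} and \code{max_lr} with exponentially decaying amplitude)
#'   or \code{"step_decay"} (\code{lr * lr_decay^floor((epoch-1)/lr_step)}).
#' @param base_lr,max_lr,half_cycle,gamma Exponential-cyclical policy
#'   parameters (iteration based).
#' @param lr,lr_decay,lr_step Step-decay policy parameters (epoch based).
#' @param seed Master seed: weight init, shuffling, dropout and the
#'   per-epoch dummy-bias redraws all derive from it.
#' @param min_dc_batch Minimum (control-)sample count for the decorrelation
#'   term; smaller batches contribute no DC term and are flagged in the
#'   history, default 8.
#' @param dc_warmup Fraction of total iterations over which the
#'   decorrelation weight ramps linearly from 0 to its full value (0 =
#'   constant weight). Letting cross-entropy shape the features first makes
#'   the penalty act on formed representations instead of freezing random
#'   ones.
#' @param augment Apply random augmentation to each training batch.
#' @param verbose Print a line per epoch.
#' @return An object of class \code{dccnn_control}.
#' @export
dccnn_control <- function(optimizer = c("rmsprop", "adam"), batch_size = 128L,
                          epochs = 10L, lr_policy = c("exp_cyclical", "step_decay"),
                          base_lr = 1e-4, max_lr = 1e-2, half_cycle = 2000L,
                          gamma = 0.99994, lr = 1e-3, lr_decay = 0.5,
                          lr_step = 5L, seed = 1L, min_dc_batch = 8L,
                          dc_warmup = 0, augment = FALSE, verbose = FALSE) {
  structure(list(optimizer = match.arg(optimizer),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_policy = match.arg(lr_policy),
                 base_lr = base_lr, max_lr = max_lr,
                 half_cycle = as.integer(half_cycle), gamma = gamma, lr = lr,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 seed = as.integer(seed), min_dc_batch = as.integer(min_dc_batch),
                 dc_warmup = dc_warmup,
                 augment = isTRUE(augment), verbose = isTRUE(verbose)),
            class = "dccnn_control")
}

#' Exponential cyclical learning rate
#'
#' Triangular cycling between \code{base_lr} and \code{max_lr} whose
#' amplitude shrinks by \code{gamma^iteration} (the exp-range flavour of
#' cyclical learning schedules).
#'
#' @param iteration 0-based iteration counter (scalar or vector).
#' @param base_lr,max_lr Cycle bounds, \code{base_lr < max_lr}.
#' @param half_cycle Iterations per half cycle.
#' @param gamma Amplitude decay per iteration, in (0, 1].
#' @return Learning rate(s).
#' @export
exp_cyclical_lr <- function(iteration, base_lr, max_lr, half_cycle, gamma = 1) {
  if (base_lr >= max_lr) stop("need base_lr < max_lr")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  cycle <- floor(1 + iteration / (2 * half_cycle))
  x <- abs(iteration / half_cycle - 2 * cycle + 1)
  base_lr + (max_lr - base_lr) * pmax(0, 1 - x) * gamma^iteration
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + as.numeric(k) * 65537) %% 2146483647)
}

#' Fit a (decorrelated) convolutional neural network
#'
#' Trains the network of \code{arch} on the training split of \code{data}
#' under \code{objective}, logging every iteration's loss terms and evaluated
#' squared distance correlation. The checkpoint with the best validation
#' balanced accuracy is retained as the fitted model.
#'
#' For the class-bias objective the dummy bias variable is redrawn each epoch
#' from a seeded substream; for the scanner objective the bias variable is
#' built according to \code{objective$bias}: standardized voxel metadata
#' (statistics fit on the training split), frozen FE-model features
#' (requires \code{fe_model}), or the temporal standard-deviation map
#' (temporal datasets).
#'
#' @param data A \code{slice_dataset}; if it has no \code{split} column a
#'   70/15/15 subject-grouped split is assigned using the control seed.
#' @param arch A [dc_architecture()].
#' @param objective A [plain_objective()], [class_bias_objective()] or
#'   [scanner_objective()].
#' @param control A [dccnn_control()].
#' @param fe_model Fitted FE scanner model (only for
#'   \code{objective$bias == "fe_features"}).
#' @return An object of class \code{dccnn} with elements \code{net} (best
#'   checkpoint), \code{final_net}, \code{history}, \code{classes},
#'   \code{val_ba}, and the specs used.
#' @export
dccnn <- function(data, arch, objective = plain_objective(),
                  control = dccnn_control(), fe_model = NULL) {
  stopifnot(inherits(data, "slice_dataset"), inherits(arch, "dccnn_arch"),
            inherits(objective, "dccnn_objective"),
            inherits(control, "dccnn_control"))
  if (is.null(data$manifest$split)) data <- split_subjects(data, seed = control$seed)

  if (arch$temporal) {
    ts <- get_timeseries(data)
    xs <- ts$series; man <- ts$manifest
  } else {
    xs <- data$images; man <- data$manifest
  }
  classes <- sort(unique(man$class), method = "radix")
  tr <- which(man$split == "train")
  va <- which(man$split == "val")
  if (!length(tr)) stop("empty training split")

  # resolve objective defaults from the training split
  if (objective$kind == "class_bias" && is.null(objective$class_weights)) {
    objective$class_weights <- inverse_frequency_weights(man$class[tr])
  }
  scanner_id <- man$scanner_id
  if (objective$kind == "scanner" && is.null(objective$scanner_weights)) {
    ctrl_tr <- tr[man$class[tr] == objective$control_label]
    if (length(unique(scanner_id[ctrl_tr])) >= 2L) {
      objective$scanner_weights <- inverse_frequency_weights(scanner_id[ctrl_tr])
    }
  }

  # static bias variables (scanner objectives); class-bias B is drawn per epoch
  bias_static <- NULL
  bias_info <- NULL
  if (objective$kind == "scanner") {
    if (objective$bias == "voxel_size") {
      vb <- voxel_size_bias(man[tr, , drop = FALSE])
      bias_info <- list(center = attr(vb, "center"), scale = attr(vb, "scale"))
      bias_static <- matrix(NA_real_, nrow(man), ncol(vb))
      bias_static[tr, ] <- vb
    } else if (objective$bias == "fe_features") {
      if (is.null(fe_model)) stop("fe_features bias needs a fitted fe_model")
      bias_static <- fe_feature_bias(fe_model, xs)
    } else {
      if (!arch$temporal) {
        stop("the temporal_std bias variable requires the temporal (ConvGRU) architecture")
      }
      bias_static <- temporal_std_bias(xs)
    }
  }

  net <- build_model(arch, seed = control$seed)
  net$classes <- classes
  state <- opt_init(net)
  tap_idx <- net$taps[arch$taps]
  lam <- switch(objective$kind, plain = 0, class_bias = objective$lambda,
                scanner = objective$lambda2)

  fetch_train <- function(sel) {
    idx <- tr[sel]
    as_batch(if (arch$temporal) xs[, , , idx, drop = FALSE] else
      xs[, , idx, drop = FALSE], arch$temporal)
  }

  set.seed(derive_seed(control$seed, 1L))
  hist_rows <- vector("list", 1000L)
  hr <- 0L
  it <- 0L
  best <- list(ba = -Inf, net = net)
  n_batches <- ceiling(length(tr) / control$batch_size)
  warm_iters <- control$dc_warmup * n_batches * control$epochs

  for (epoch in seq_len(control$epochs)) {
    bias_epoch <- bias_static
    if (objective$kind == "class_bias" && lam > 0) {
      be <- dummy_class_bias(man$class[tr], objective$width_majority,
                             objective$width_minority,
                             seed = derive_seed(control$seed, 100L + epoch))
      bias_epoch <- matrix(NA_real_, nrow(man), 1L)
      bias_epoch[tr, ] <- be
    }
    ord <- sample(tr)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * control$batch_size + 1L):
                   min(bi * control$batch_size, length(ord))]
      if (length(idx) < 2L) next
      xb <- if (arch$temporal) xs[, , , idx, drop = FALSE] else
        xs[, , idx, drop = FALSE]
      if (control$augment && !arch$temporal) {
        xb <- shift_flip_batch(xb, seed = derive_seed(control$seed, 1e5 + it))
      }
      yb <- man$class[idx]
      lr <- if (control$lr_policy == "exp_cyclical") {
        exp_cyclical_lr(it, control$base_lr, control$max_lr,
                        control$half_cycle, control$gamma)
      } else {
        control$lr * control$lr_decay^((epoch - 1L) %/% control$lr_step)
      }

      fw <- net_forward(net, as_batch(xb, arch$temporal), training = TRUE)
      net <- fw$net                       # adopt updated BN running stats
      probs <- fw$out
      colnames(probs) <- classes
      n <- length(idx)
      Y <- diag(length(classes))[match(yb, classes), , drop = FALSE]
      cw <- if (objective$kind == "class_bias") {
        as.numeric(objective$class_weights[yb])
      } else rep(1, n)
      ce_scale <- if (objective$kind == "scanner") objective$lambda1 else 1
      pclip <- pmax(probs, 1e-7)
      ce <- ce_scale * mean(-cw * log(pclip[cbind(seq_len(n), match(yb, classes))]))
      dout <- -(Y / pclip) * (ce_scale * cw / n)

      # decorrelation term and its gradient injected at the taps
      dc2 <- NA_real_; dc_term <- 0; skipped <- FALSE
      lam_t <- if (warm_iters > 0) lam * min(1, it / warm_iters) else lam
      inject <- NULL
      if (lam > 0) {
        rows <- if (objective$kind == "scanner") {
          which(yb == objective$control_label)
        } else seq_len(n)
        if (length(rows) < control$min_dc_batch) {
          skipped <- TRUE
        } else {
          fmat <- gather_taps(fw, tap_idx)
          bmat <- bias_epoch[idx[rows], , drop = FALSE]
          wv <- if (objective$kind == "scanner") {
            if (anyNA(scanner_id[idx[rows]])) {
              stop("missing scanner id on a control sample")
            }
            scanner_sample_weights(objective$scanner_weights,
                                   scanner_id[idx[rows]])
          } else NULL
          gg <- dcor_sq_grad(bmat, fmat[rows, , drop = FALSE], wv)
          dc2 <- gg$value
          dc_term <- lam_t * dc2
          gfull <- matrix(0, n, ncol(fmat))
          gfull[rows, ] <- lam_t * gg$grad
          inject <- split_tap_grad(gfull, fw, tap_idx)
        }
      }

      l2v <- objective$l2 * l2_penalty(net)
      total <- ce + dc_term + l2v
      if (!is.finite(total)) {
        stop(sprintf("non-finite loss at iteration %d (ce=%.4g, dc=%.4g, l2=%.4g)",
                     it, ce, dc_term, l2v))
      }

      bw <- net_backward(net, fw, dout, inject = inject)
      grads <- add_l2_grads(net, bw$grads, objective$l2)
      st <- opt_step(net, grads, state, lr, control$optimizer, it + 1L)
      net <- st$net; state <- st$state
      it <- it + 1L

      hr <- hr + 1L
      if (hr > length(hist_rows)) hist_rows <- c(hist_rows, vector("list", 1000L))
      hist_rows[[hr]] <- data.frame(iteration = it, epoch = epoch, lr = lr,
                                    loss = total, ce = ce, dc2 = dc2,
                                    dc_term = dc_term, l2 = l2v,
                                    dc_skipped = skipped)
    }
    # validation checkpointing on balanced accuracy, after exact BN
    # re-estimation on the training data
    netc <- calibrate_bn(net, fetch_train, length(tr), control$batch_size)
    if (length(va)) {
      vp <- net_predict(netc, if (arch$temporal) xs[, , , va, drop = FALSE] else
        xs[, , va, drop = FALSE])
      colnames(vp) <- classes
      pred <- classes[max.col(vp, ties.method = "first")]
      ba <- balanced_accuracy_value(man$class[va], pred, classes)
      if (is.finite(ba) && ba > best$ba) best <- list(ba = ba, net = netc)
      if (control$verbose) {
        message(sprintf("epoch %d: loss %.4f, val BA %.1f%%", epoch,
                        hist_rows[[hr]]$loss, ba))
      }
    }
  }
  netc <- calibrate_bn(net, fetch_train, length(tr), control$batch_size)
  if (!is.finite(best$ba)) best <- list(ba = NA_real_, net = netc)
  structure(list(net = best$net, final_net = netc,
                 history = do.call(rbind, hist_rows[seq_len(hr)]),
                 classes = classes, arch = arch, objective = objective,
                 control = control, val_ba = best$ba,
                 bias_info = bias_info,
                 n_train = length(tr), n_params = net_param_count(net)),
            class = "dccnn")
}

# Slice a concatenated tap-gradient matrix back into per-layer injections.
split_tap_grad <- function(g, fw, tap_idx) {
  inject <- list()
  off <- 0L
  for (ti in seq_along(tap_idx)) {
    i <- tap_idx[ti]
    o <- fw$outs[[i]]
    if (is.matrix(o)) {
      d <- ncol(o)
      gi <- g[, (off + 1L):(off + d), drop = FALSE]
    } else {
      dd <- dim(o)
      d <- prod(dd[-3L])
      gi <- unflatten_spatial(g[, (off + 1L):(off + d), drop = FALSE], dd)
    }
    key <- as.character(i)
    inject[[key]] <- if (is.null(inject[[key]])) gi else inject[[key]] + gi
    off <- off + d
  }
  inject
}

balanced_accuracy_value <- function(truth, pred, classes) {
  recalls <- vapply(classes, function(cl) {
    n <- sum(truth == cl)
    if (n == 0L) return(NA_real_)
    sum(truth == cl & pred == cl) / n
  }, 0)
  mean(recalls, na.rm = TRUE) * 100
}

#' Replicate a fit across seeds
#'
#' Retrains the same configuration \code{n_runs} times with consecutive
#' seeds, the protocol used to report mean and 95\% interval across
#' initializations.
#'
#' @param data,arch,objective,control,fe_model As in [dccnn()].
#' @param n_runs Number of runs, default 3.
#' @return List of \code{dccnn} fits, class \code{dccnn_runs}.
#' @export
dccnn_replicate <- function(data, arch, objective = plain_objective(),
                            control = dccnn_control(), n_runs = 3L,
                            fe_model = NULL) {
  fits <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    ctl <- control
    ctl$seed <- control$seed + r - 1L
    fits[[r]] <- dccnn(data, arch, objective, ctl, fe_model = fe_model)
  }
  structure(fits, class = "dccnn_runs")
}

#' Mean and 95 percent t-interval across runs
#'
#' \eqn{\bar x \pm t_{0.975, n-1} \cdot s/\sqrt{n}} (t = 4.303 for n = 3).
#' With a single value the interval is undefined and only the mean is
#' returned.
#'
#' @param values Numeric vector of per-run metric values.
#' @return List with \code{mean}, \code{half_width}, \code{lower},
#'   \code{upper}, \code{n}.
#' @export
run_interval <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("no finite values")
  m <- mean(values)
  if (n < 2L) {
    return(list(mean = m, half_width = NA_real_, lower = NA_real_,
                upper = NA_real_, n = n))
  }
  hw <- stats::qt(0.975, df = n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, half_width = hw, lower = m - hw, upper = m + hw, n = n)
}

# --- S3 methods ------------------------------------------------------------

#' @export
print.dccnn <- function(x, ...) {
  cat("Decorrelated CNN fit (", x$arch$variant, ", objective: ",
      x$objective$kind, ")\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = " / "),
      "  parameters:", x$n_params, "\n")
  cat("  training slices:", x$n_train, " epochs:", x$control$epochs,
      " batch:", x$control$batch_size, " seed:", x$control$seed, "\n")
  if (is.finite(x$val_ba)) {
    cat(sprintf("  best validation balanced accuracy: %.1f%%\n", x$val_ba))
  }
  invisible(x)
}

#' @export
summary.dccnn <- function(object, ...) {
  h <- object$history
  cat("Call objective:\n"); print(object$objective)
  print(object$arch)
  cat(sprintf("final loss %.4f (ce %.4f, dc %.4f, l2 %.4f) after %d iterations\n",
              h$loss[nrow(h)], h$ce[nrow(h)], h$dc_term[nrow(h)],
              h$l2[nrow(h)], nrow(h)))
  if (any(is.finite(h$dc2))) {
    d <- h$dc2[is.finite(h$dc2)]
    k <- max(1L, length(d) %/% 10L)
    cat(sprintf("DC^2 first-decile mean %.4f -> last-decile mean %.4f\n",
                mean(d[seq_len(k)]), mean(d[(length(d) - k + 1L):length(d)])))
  }
  if (is.finite(object$val_ba)) {
    cat(sprintf("best validation balanced accuracy: %.1f%%\n", object$val_ba))
  }
  invisible(object)
}

#' Predict from a fitted DcCNN
#'
#' @param object A fitted [dccnn()].
#' @param newdata A \code{slice_dataset} or an image array (\code{(H, W, N)},
#'   or temporal \code{(H, W, T, N)}).
#' @param type \code{"prob"} (class probability matrix), \code{"class"}
#'   (predicted labels), or \code{"feature"} (concatenated tap features).
#' @param taps Tap names for \code{type = "feature"}.
#' @param ... Unused.
#' @export
predict.dccnn <- function(object, newdata, type = c("prob", "class", "feature"),
                          taps = NULL, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "slice_dataset")) {
    if (object$arch$temporal) get_timeseries(newdata)$series else newdata$images
  } else newdata
  if (type == "feature") return(extract_features(object$net, x, taps))
  p <- net_predict(object$net, x)
  colnames(p) <- object$classes
  if (type == "prob") p else
    factor(object$classes[max.col(p, ties.method = "first")],
           levels = object$classes)
}

#' @export
coef.dccnn <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$net$layers)) {
    ly <- object$net$layers[[i]]
    nm <- paste0(ly$type, i)
    if (ly$type %in% c("conv", "dense")) out[[nm]] <- list(W = ly$W, b = ly$b)
    if (ly$type == "bnorm") out[[nm]] <- list(gamma = ly$gamma, beta = ly$beta)
    if (ly$type == "convgru") out[[nm]] <- ly$params[c("Wxz", "Whz", "bz",
                                                      "Wxr", "Whr", "br",
                                                      "Wxh", "Whh", "bh")]
  }
  out
}

#' @export
residuals.dccnn <- function(object, newdata, positive = NULL, ...) {
  p <- predict(object, newdata, type = "prob")
  if (is.null(positive)) positive <- object$classes[length(object$classes)]
  truth <- if (inherits(newdata, "slice_dataset")) {
    m <- if (object$arch$temporal) get_timeseries(newdata)$manifest else
      newdata$manifest
    m$class
  } else stop("residuals need a slice_dataset with labels")
  as.numeric(truth == positive) - p[, positive]
}

#' Plot training diagnostics
#'
#' Two panels: the total loss per iteration, and the evaluated squared
#' distance correlation between features and the bias variable (when a
#' decorrelation term is active) — the curve whose downward trend shows the
#' penalty doing its work.
#'
#' @param x A fitted [dccnn()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dccnn <- function(x, ...) {
  h <- x$history
  has_dc <- any(is.finite(h$dc2))
  op <- graphics::par(mfrow = c(if (has_dc) 2 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$loss, type = "l", xlab = "iteration",
                 ylab = "total loss", main = "training loss", ...)
  if (has_dc) {
    graphics::plot(h$iteration, h$dc2, type = "l", xlab = "iteration",
                   ylab = expression(DC^2), main = "feature-bias decorrelation",
                   ...)
  }
  invisible(x)
}


# Fast per-batch augmentation: random integer translation (zero-filled) and
# horizontal flips. Cheap enough to run on every training batch; the heavier
# rotation/elastic pipeline lives in augment_slices().
shift_flip_batch <- function(x, translation = 3L, seed = 1L) {
  d <- dim(x)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sh <- matrix(sample(-translation:translation, 2L * d[3], replace = TRUE),
               ncol = 2L)
  fl <- stats::runif(d[3]) < 0.5
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    img <- x[, , i]
    if (fl[i]) img <- img[, rev(seq_len(d[2]))]
    sr <- sh[i, 1]; sc <- sh[i, 2]
    r_src <- max(1, 1 - sr):min(d[1], d[1] - sr)
    c_src <- max(1, 1 - sc):min(d[2], d[2] - sc)
    out[r_src + sr, c_src + sc, i] <- img[r_src, c_src]
  }
  out
}
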