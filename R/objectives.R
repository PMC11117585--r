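# The composite training objectives: cross-entropy + decorrelation + L2.
#
# Two forms are used. For class-bias mitigation the loss is
#   L_WCE(Y, Yhat) + lambda * DC^2(B, F) + l2 * ||theta||^2
# with B a dummy class-bias variable. For scanner-bias mitigation it is
#   lambda1 * L(Y, Yhat) + lambda2 * DC^2_control(B, F) + l2 * ||theta||^2
# where the decorrelation term is restricted to control-class samples (the
# only class scanned on both scanners) and uses per-scanner sample weights.

#' Plain cross-entropy objective (baseline)
#'
#' Softmax cross-entropy plus L2; no decorrelation, no class weights. The
#' reference objective against which the decorrelated variants are compared.
#'
#' @param l2 L2 (weight decay) coefficient.
#' @return An object of class \code{dccnn_objective}.
#' @export
plain_objective <- function(l2 = 1e-4) {
  structure(list(kind = "plain", lambda = 0, class_weights = NULL, l2 = l2),
            class = "dccnn_objective")
}

#' Class-bias decorrelation objective
#'
#' Weighted cross-entropy plus \eqn{\lambda \cdot DC^2(B, F)} plus L2, where B
#' is the dummy class-bias variable and F the concatenated feature taps.
#' With \code{lambda = 0} this reduces exactly to weighted cross-entropy +
#' L2.
#'
#' @param lambda Weight of the decorrelation term, default 0.2.
#' @param class_weights Named per-class weights for the cross-entropy;
#'   \code{NULL} computes inverse-frequency weights on the training labels.
#' @param l2 L2 coefficient.
#' @param width_majority,width_minority Supports of the dummy bias variable.
#' @return An object of class \code{dccnn_objective}.
#' @export
class_bias_objective <- function(lambda = 0.2, class_weights = NULL, l2 = 1e-4,
                                 width_majority = 10L, width_minority = 2L) {
  if (lambda < 0 || l2 < 0) stop("lambda and l2 must be nonnegative")
  structure(list(kind = "class_bias", lambda = lambda,
                 class_weights = class_weights, l2 = l2,
                 width_majority = width_majority,
                 width_minority = width_minority),
            class = "dccnn_objective")
}

#' Scanner-bias decorrelation objective
#'
#' \eqn{\lambda_1} cross-entropy over all samples plus \eqn{\lambda_2} times
#' the sample-weighted squared distance correlation between the scanner-bias
#' variable and the features of control-class samples, plus L2. Restricting
#' decorrelation to controls removes scanner information without removing the
#' disease signal, because only controls appear on both scanners.
#'
#' @param lambda1,lambda2 Trade-off weights for cross-entropy and
#'   decorrelation (defaults 0.5 and 5.0).
#' @param control_label The class on which decorrelation applies, default
#'   \code{"control"}.
#' @param scanner_weights Named per-scanner weights used inside the weighted
#'   dCor; \code{NULL} computes inverse scanner frequency among training
#'   controls, normalized to mean 1, so both scanners are decorrelated
#'   equally despite cohort imbalance.
#' @param l2 L2 coefficient, default 0.005.
#' @param bias Scanner-bias variable type: \code{"voxel_size"},
#'   \code{"fe_features"} or \code{"temporal_std"}.
#' @return An object of class \code{dccnn_objective}.
#' @export
scanner_objective <- function(lambda1 = 0.5, lambda2 = 5.0,
                              control_label = "control",
                              scanner_weights = NULL, l2 = 0.005,
                              bias = c("voxel_size", "fe_features",
                                       "temporal_std")) {
  if (lambda1 < 0 || lambda2 < 0 || l2 < 0) stop("weights must be nonnegative")
  structure(list(kind = "scanner", lambda1 = lambda1, lambda2 = lambda2,
                 control_label = control_label,
                 scanner_weights = scanner_weights, l2 = l2,
                 bias = match.arg(bias)),
            class = "dccnn_objective")
}

#' @export
print.dccnn_objective <- function(x, ...) {
  cat("DcCNN objective:", x$kind, "\n")
  if (x$kind == "scanner") {
    cat("  lambda1 (CE):", x$lambda1, " lambda2 (dCor):", x$lambda2,
        " control label:", x$control_label, " bias:", x$bias, "\n")
  } else {
    cat("  lambda (dCor):", x$lambda, "\n")
  }
  cat("  l2:", x$l2, "\n")
  invisible(x)
}

#' Weighted cross-entropy
#'
#' Mean over samples of \eqn{-w_{y_i} \log p_i(y_i)} with per-class weights.
#' Probabilities are clipped at \code{clip} before the log.
#'
#' @param y_true Label vector; every label must appear among the columns of
#'   \code{y_pred}.
#' @param y_pred Probability matrix with one named column per class; rows
#'   must sum to 1 within 1e-6.
#' @param class_weights Named per-class weights; \code{NULL} means uniform.
#' @param clip Probability floor, default 1e-7.
#' @return Nonnegative scalar.
#' @export
weighted_cross_entropy <- function(y_true, y_pred, class_weights = NULL,
                                   clip = 1e-7) {
  y_true <- as.character(y_true)
  if (is.null(colnames(y_pred))) stop("y_pred needs class column names")
  bad <- setdiff(unique(y_true), colnames(y_pred))
  if (length(bad)) stop("label(s) outside the class set: ",
                        paste(bad, collapse = ", "))
  if (any(abs(rowSums(y_pred) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  if (is.null(class_weights)) {
    class_weights <- stats::setNames(rep(1, ncol(y_pred)), colnames(y_pred))
  }
  p <- pmax(y_pred[cbind(seq_along(y_true), match(y_true, colnames(y_pred)))],
            clip)
  mean(-as.numeric(class_weights[y_true]) * log(p))
}

#' Evaluate a composite objective with a per-term breakdown
#'
#' Computes the total loss of an objective on a batch, offline, together with
#' its cross-entropy, decorrelation and L2 terms. The same arithmetic is used
#' inside the training loop; this function exists so the logged terms can be
#' recomputed and audited.
#'
#' @param model A fitted [dccnn] or a \code{dccnn_net}.
#' @param images Batch image stack \code{(H, W, N)} (or temporal array).
#' @param labels Class labels for the batch.
#' @param objective A \code{dccnn_objective}.
#' @param bias BiasVariable matrix aligned with the batch rows (ignored for
#'   \code{plain}).
#' @param scanner_id Per-sample scanner ids (scanner objective only).
#' @param taps Tap names; default the architecture's.
#' @param min_dc_batch Minimum sample count for the decorrelation term,
#'   default 8; below it the DC term is 0 and flagged.
#' @return List with \code{total}, \code{ce}, \code{dc2}, \code{dc_term},
#'   \code{l2}, \code{dc_skipped}.
#' @export
evaluate_objective <- function(model, images, labels, objective, bias = NULL,
                               scanner_id = NULL, taps = NULL,
                               min_dc_batch = 8L) {
  net <- if (inherits(model, "dccnn")) model$net else model
  if (is.null(taps)) taps <- net$arch$taps
  probs <- net_predict(net, images)
  colnames(probs) <- net$classes %||% colnames(probs) %||%
    as.character(seq_len(ncol(probs)) - 1L)
  f <- extract_features(net, images, taps)
  breakdown_from(probs, f, labels, objective, bias, scanner_id,
                 l2_value = l2_penalty(net), min_dc_batch = min_dc_batch)
}

# Shared arithmetic for the trainer and evaluate_objective().
breakdown_from <- function(probs, f, labels, objective, bias, scanner_id,
                           l2_value, min_dc_batch = 8L) {
  labels <- as.character(labels)
  kind <- objective$kind
  dc2 <- 0; dc_term <- 0; skipped <- FALSE
  if (kind == "plain") {
    ce <- weighted_cross_entropy(labels, probs, NULL)
    lam <- 0
  } else if (kind == "class_bias") {
    ce <- weighted_cross_entropy(labels, probs, objective$class_weights)
    lam <- objective$lambda
    if (lam > 0) {
      if (nrow(f) < min_dc_batch) {
        skipped <- TRUE
      } else {
        dc2 <- distance_correlation_sq(bias, f)
        dc_term <- lam * dc2
      }
    }
  } else {
    ce <- objective$lambda1 * weighted_cross_entropy(labels, probs, NULL)
    ctrl <- which(labels == objective$control_label)
    if (objective$lambda2 > 0) {
      if (length(ctrl) < min_dc_batch) {
        skipped <- TRUE
      } else {
        if (is.null(scanner_id)) stop("scanner objective needs scanner ids")
        if (anyNA(scanner_id[ctrl])) {
          stop("missing scanner id on a control sample")
        }
        w <- scanner_sample_weights(objective$scanner_weights,
                                    scanner_id[ctrl])
        dc2 <- weighted_distance_correlation_sq(bias[ctrl, , drop = FALSE],
                                                f[ctrl, , drop = FALSE], w)
        dc_term <- objective$lambda2 * dc2
      }
    }
  }
  l2 <- objective$l2 * l2_value
  list(total = ce + dc_term + l2, ce = ce, dc2 = dc2, dc_term = dc_term,
       l2 = l2, dc_skipped = skipped)
}

# Map named per-scanner weights onto samples; NULL weights mean uniform.
scanner_sample_weights <- function(scanner_weights, scanner_id) {
  if (is.null(scanner_weights)) return(rep(1, length(scanner_id)))
  miss <- setdiff(unique(scanner_id), names(scanner_weights))
  if (length(miss)) stop("no scanner weight for: ", paste(miss, collapse = ", "))
  as.numeric(scanner_weights[as.character(scanner_id)])
}
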