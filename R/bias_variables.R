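# Constructions of the per-sample bias variable B fed to the decorrelation
# penalty. Bias variables are inputs: they never receive gradients.

#' Dummy class-bias variable
#'
#' Draws, for every sample, an integer from a discrete uniform distribution
#' whose support width depends on the sample's class: the majority class gets
#' the wider support. The draw correlates with the class label by
#' construction and thereby encodes the class-imbalance shortcut that the
#' decorrelation penalty is meant to remove. It is redrawn every epoch during
#' training.
#'
#' @param labels Class label vector.
#' @param width_majority,width_minority Support sizes \code{{0, ..., width-1}};
#'   the majority width must be strictly larger.
#' @param seed Integer seed; draws are reproducible and do not disturb the
#'   caller's RNG stream.
#' @param majority Optional explicit majority class; defaults to the modal
#'   label.
#' @return One-column matrix with attributes \code{kind} and
#'   \code{provenance}.
#' @export
dummy_class_bias <- function(labels, width_majority = 10L, width_minority = 2L,
                             seed = 1L, majority = NULL) {
  if (width_minority < 1L || width_majority <= width_minority) {
    stop("need width_majority > width_minority >= 1 (equal widths carry no bias signal)")
  }
  tab <- table(labels)
  if (is.null(majority)) majority <- names(tab)[which.max(tab)]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  widths <- ifelse(labels == majority, width_majority, width_minority)
  b <- matrix(floor(stats::runif(length(labels)) * widths), ncol = 1L)
  structure(b, kind = "dummy_class",
            provenance = list(width_majority = width_majority,
                              width_minority = width_minority, seed = seed,
                              majority = majority))
}

#' Voxel-size scanner-bias variable
#'
#' Per-sample rows of (slice thickness, pixel spacing x, pixel spacing y) in
#' mm, standardized to zero mean / unit variance. Standardization statistics
#' are fit on the training split and must be reused verbatim for other
#' splits via \code{center}/\code{scale}.
#'
#' @param manifest Manifest data frame carrying
#'   \code{slice_thickness_mm, pixel_spacing_x_mm, pixel_spacing_y_mm}.
#' @param center,scale Optional standardization statistics (length 3). When
#'   \code{NULL} they are fit on \code{manifest} and attached as attributes.
#' @return n x 3 matrix with attributes \code{kind}, \code{center},
#'   \code{scale}.
#' @export
voxel_size_bias <- function(manifest, center = NULL, scale = NULL) {
  cols <- c("slice_thickness_mm", "pixel_spacing_x_mm", "pixel_spacing_y_mm")
  miss <- setdiff(cols, names(manifest))
  if (length(miss)) stop("manifest lacks voxel metadata column(s): ",
                         paste(miss, collapse = ", "))
  b <- as.matrix(manifest[, cols])
  bad <- which(!stats::complete.cases(b))
  if (length(bad)) {
    stop("missing voxel metadata for subject(s): ",
         paste(unique(manifest$subject_id[bad]), collapse = ", "))
  }
  if (is.null(center)) center <- colMeans(b)
  if (is.null(scale)) {
    scale <- apply(b, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  b <- sweep(sweep(b, 2L, center, "-"), 2L, scale, "/")
  structure(b, kind = "voxel_size", center = center, scale = scale)
}

#' Scanner-classifier feature bias variable
#'
#' Flattened activations of the feature-extraction (FE) scanner classifier's
#' deepest conv block, computed with the FE model frozen. The FE model is a
#' fitted network trained to predict the scanner from control images; its
#' features carry concentrated scanner information and serve as a rich bias
#' variable.
#'
#' @param fe_model A fitted [dccnn] object (the trained FE scanner model).
#' @param images Image stack \code{(H, W, N)}.
#' @param taps Tap name(s) to extract, default the deepest conv block.
#' @return n x d matrix with attribute \code{kind}.
#' @export
fe_feature_bias <- function(fe_model, images, taps = NULL) {
  if (!inherits(fe_model, "dccnn")) {
    stop("fe_model must be a trained model (a fitted 'dccnn' object)")
  }
  if (is.null(taps)) {
    conv_taps <- grep("^conv", names(fe_model$net$taps), value = TRUE)
    taps <- conv_taps[length(conv_taps)]
  }
  b <- extract_features(fe_model, images, taps = taps)
  structure(b, kind = "fe_features", taps = taps)
}

#' Temporal-fluctuation scanner-bias variable
#'
#' Per-pixel population standard deviation over the T frames of each series,
#' average-pooled spatially and flattened: a compact map of the scanner's
#' temporal noise level.
#'
#' @param series Array \code{(H, W, T, M)} of M frame series, or
#'   \code{(H, W, T)} for a single series.
#' @param pool Average-pooling factor, default 4.
#' @return M x d matrix with attribute \code{kind}.
#' @export
temporal_std_bias <- function(series, pool = 4L) {
  d <- dim(series)
  if (length(d) == 3L) { dim(series) <- c(d, 1L); d <- dim(series) }
  if (d[3] < 2L) stop("need at least T = 2 frames for a temporal std")
  h <- d[1]; w <- d[2]; Tn <- d[3]; m <- d[4]
  mu <- apply(series, c(1, 2, 4), mean)
  mu2 <- apply(series^2, c(1, 2, 4), mean)
  sdmap <- sqrt(pmax(mu2 - mu^2, 0))            # (H, W, M), population std
  hp <- h %/% pool; wp <- w %/% pool
  out <- matrix(0, m, hp * wp)
  for (i in seq_len(m)) {
    sm <- sdmap[seq_len(hp * pool), seq_len(wp * pool), i]
    dim(sm) <- c(pool, hp, pool, wp)
    out[i, ] <- as.vector(apply(sm, c(2, 4), mean))
  }
  structure(out, kind = "temporal_std", pool = pool)
}
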