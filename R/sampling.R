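# Sampling baselines and class-weight computation for imbalanced training.
# All resampling applies to the training split only; validation and test
# rows are never touched, and resampled records carry a provenance flag.

train_rows <- function(ds) {
  if (!is.null(ds$manifest$split)) which(ds$manifest$split == "train")
  else seq_len(nrow(ds$manifest))
}

#' Random oversampling (ROS)
#'
#' Duplicates minority-class training records at random (with replacement)
#' until both classes have equal training counts. Duplicated records are
#' exact copies, flagged in \code{manifest$resampled}.
#'
#' @param ds A \code{slice_dataset} (with a \code{split} column; only the
#'   training split is resampled).
#' @param seed Seed for the duplicate draws.
#' @return The augmented \code{slice_dataset}.
#' @export
random_oversample <- function(ds, seed = 1L) {
  tr <- train_rows(ds)
  cls <- ds$manifest$class[tr]
  tab <- table(cls)
  if (length(tab) < 2L) stop("random oversampling needs two classes")
  ds$manifest$resampled <- FALSE
  if (length(unique(as.integer(tab))) == 1L) return(ds)
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- sample(tr[cls == minority], need, replace = TRUE)
  add_rows(ds, pick)
}

add_rows <- function(ds, pick) {
  if (!length(pick)) return(ds)
  new_man <- ds$manifest[pick, , drop = FALSE]
  new_man$resampled <- TRUE
  ds$images <- array(c(ds$images, ds$images[, , pick]),
                     c(dim(ds$images)[1:2], dim(ds$images)[3] + length(pick)))
  ds$manifest <- rbind(ds$manifest, new_man)
  rownames(ds$manifest) <- NULL
  ds
}

#' Balanced stratified resampling
#'
#' Resamples every class stratum of the training split (with replacement) to
#' the majority-class size, so the strata end up balanced.
#'
#' @inheritParams random_oversample
#' @return The resampled \code{slice_dataset}.
#' @export
stratified_balanced_split <- function(ds, seed = 1L) {
  tr <- train_rows(ds)
  cls <- ds$manifest$class[tr]
  tab <- table(cls)
  if (any(tab == 0L) || length(tab) < 2L) stop("every stratum must be non-empty")
  ds$manifest$resampled <- FALSE
  target <- max(tab)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- integer(0)
  for (cl in sort(names(tab), method = "radix")) {
    if (tab[[cl]] < target) {
      pick <- c(pick, sample(tr[cls == cl], target - tab[[cl]], replace = TRUE))
    }
  }
  add_rows(ds, pick)
}

#' SMOTE: synthetic minority oversampling
#'
#' Creates synthetic minority rows by convex interpolation between a minority
#' sample and one of its k nearest minority neighbours:
#' \eqn{x_{new} = x + u (x_{nn} - x)}, \eqn{u \sim U(0,1)}.
#'
#' @param x Numeric feature matrix (images should be flattened to rows first;
#'   see [smote_images()]).
#' @param labels Class labels aligned with the rows of \code{x}.
#' @param k Number of nearest neighbours, default 5; the minority count must
#'   exceed k.
#' @param seed Seed for parent/neighbour/interpolation draws.
#' @param n_new Number of synthetic rows; default tops the minority class up
#'   to the majority count.
#' @return Matrix of synthetic rows with attribute \code{class} (the minority
#'   label).
#' @export
smote_oversample <- function(x, labels, k = 5L, seed = 1L, n_new = NULL) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("SMOTE needs two classes")
  minority <- names(tab)[which.min(tab)]
  xi <- x[labels == minority, , drop = FALSE]
  if (nrow(xi) <= k) stop("minority count must exceed k")
  if (is.null(n_new)) n_new <- max(tab) - min(tab)
  if (n_new <= 0L) return(structure(x[0, , drop = FALSE], class_label = minority))
  dmat <- as.matrix(stats::dist(xi))
  diag(dmat) <- Inf
  nn_idx <- matrix(apply(dmat, 1L, function(r) order(r)[seq_len(k)]),
                   nrow = nrow(xi), ncol = k, byrow = TRUE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  parent <- sample(nrow(xi), n_new, replace = TRUE)
  nb <- nn_idx[cbind(parent, sample(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  synth <- xi[parent, , drop = FALSE] +
    u * (xi[nb, , drop = FALSE] - xi[parent, , drop = FALSE])
  structure(synth, class_label = minority, parent = parent, neighbour = nb)
}

#' SMOTE on image stacks
#'
#' Flattens training images to rows, runs [smote_oversample()], and reshapes
#' the synthetic rows back to images appended to the dataset (training split,
#' provenance-flagged).
#'
#' @inheritParams random_oversample
#' @param k Nearest-neighbour count, default 5.
#' @return The augmented \code{slice_dataset}.
#' @export
smote_images <- function(ds, k = 5L, seed = 1L) {
  tr <- train_rows(ds)
  h <- dim(ds$images)[1]; w <- dim(ds$images)[2]
  xm <- t(matrix(ds$images[, , tr], h * w, length(tr)))
  synth <- smote_oversample(xm, ds$manifest$class[tr], k = k, seed = seed)
  if (!nrow(synth)) { ds$manifest$resampled <- FALSE; return(ds) }
  minority <- attr(synth, "class_label")
  tmpl <- ds$manifest[tr[ds$manifest$class[tr] == minority][1], , drop = FALSE]
  ds$manifest$resampled <- FALSE
  n0 <- dim(ds$images)[3]
  ds$images <- array(c(ds$images, t(synth)), c(h, w, n0 + nrow(synth)))
  new_man <- tmpl[rep(1L, nrow(synth)), , drop = FALSE]
  new_man$subject_id <- sprintf("SMOTE%04d", seq_len(nrow(synth)))
  new_man$resampled <- TRUE
  ds$manifest <- rbind(ds$manifest, new_man)
  rownames(ds$manifest) <- NULL
  ds
}

#' Inverse-frequency class weights
#'
#' \eqn{w_c = n_{total} / (n_{classes} \cdot n_c)}, normalized to mean 1, so
#' the weighted cross-entropy places proportionally more emphasis on the
#' minority class.
#'
#' @param labels Class label vector with at least two non-empty classes.
#' @return Named numeric vector of per-class weights.
#' @export
inverse_frequency_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two classes")
  if (any(tab == 0L)) stop("empty class in labels")
  w <- length(labels) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w / mean(w)
}

#' Random augmentation of slice images
#'
#' Applies a random rotation, translation, and elastic deformation to each
#' image, the standard augmentations for making slice classifiers shift,
#' rotation and deformation invariant.
#'
#' @param images Array \code{(H, W, N)}.
#' @param rotation Max |angle| in degrees, default 10.
#' @param translation Max |shift| in px, default 3.
#' @param elastic_alpha,elastic_sigma Displacement amplitude (px) and
#'   smoothing of the elastic field, defaults 8 and 2.
#' @param seed Seed; augmentation is deterministic given it.
#' @return Augmented array of the same shape.
#' @export
augment_slices <- function(images, rotation = 10, translation = 3,
                           elastic_alpha = 8, elastic_sigma = 2, seed = 1L) {
  d <- dim(images)
  if (length(d) == 2L) { dim(images) <- c(d, 1L); d <- dim(images) }
  h <- d[1]; w <- d[2]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- images
  for (i in seq_len(d[3])) {
    img <- EBImage::Image(images[, , i])
    ang <- stats::runif(1, -rotation, rotation)
    img <- EBImage::rotate(img, ang, output.dim = c(h, w), bg.col = 0)
    sh <- round(stats::runif(2, -translation, translation))
    img <- EBImage::translate(img, sh, bg.col = 0)
    m <- as.matrix(img)[seq_len(h), seq_len(w)]
    if (elastic_alpha > 0) {
      dx <- gauss_smooth(matrix(stats::runif(h * w, -1, 1), h, w),
                         elastic_sigma) * elastic_alpha
      dy <- gauss_smooth(matrix(stats::runif(h * w, -1, 1), h, w),
                         elastic_sigma) * elastic_alpha
      m <- bilinear_warp(m, dx, dy)
    }
    out[, , i] <- m
  }
  out
}

# Bilinear sampling of m at (row + dx, col + dy), clamped to the border.
bilinear_warp <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  r <- matrix(seq_len(h), h, w) + dx
  c2 <- matrix(seq_len(w), h, w, byrow = TRUE) + dy
  r <- pmin(pmax(r, 1), h); c2 <- pmin(pmax(c2, 1), w)
  r0 <- floor(r); c0 <- floor(c2)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- r - r0; fc <- c2 - c0
  g <- function(ri, ci) matrix(m[cbind(as.vector(ri), as.vector(ci))], h, w)
  (1 - fr) * (1 - fc) * g(r0, c0) + fr * (1 - fc) * g(r1, c0) +
    (1 - fr) * fc * g(r0, c1) + fr * fc * g(r1, c1)
}
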