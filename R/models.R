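#' Architecture specification for a (Dc)CNN variant
#'
#' Describes one of the named network variants or a custom stack. Named
#' variants carry their published filter counts:
#' \describe{
#'   \item{classbias_dccnn}{three conv blocks (32, 64, 128 filters), two
#'     fully connected layers, softmax head; features tapped from
#'     \code{fc1, fc2, softmax}.}
#'   \item{scanner_dccnn}{conv blocks 32, 16, 16; fc 40, 100; taps
#'     \code{conv1, fc1, fc2}.}
#'   \item{fe_model}{five conv blocks 32, 16, 16, 8, 8 with dropout 0.2 on the
#'     first four; fc 40, 100; scanner-classifier whose fifth conv block
#'     output serves as a bias variable; tap \code{conv5}.}
#'   \item{fe_dccnn}{same stack as \code{fe_model}; taps \code{conv5, fc1, fc2}.}
#'   \item{convgru_dccnn}{a convolutional GRU first layer summarizing the
#'     temporal axis, then conv blocks 16, 32, 32 and fc 1000, 500; taps
#'     \code{conv2, fc1}.}
#'   \item{custom}{any conv/fc stack, for desk-scale experiments.}
#' }
#' Each conv block is convolution (3x3, 'same' padding), ReLU, batch
#' normalization, then 2x2 max pooling. Feature taps name the block/layer
#' outputs that are flattened and concatenated into the feature matrix F fed
#' to the decorrelation penalty.
#'
#' @param variant Variant name, see above.
#' @param input_shape \code{c(H, W)} for 2D slice models, \code{c(T, H, W)}
#'   for the ConvGRU variant (T frames).
#' @param conv_filters,fc_sizes Integer vectors; defaults follow the variant.
#' @param dropout Dropout rate on the first four conv blocks (FE variants
#'   default to 0.2, others to 0).
#' @param taps Character vector of tap names (\code{conv<i>}, \code{fc1},
#'   \code{fc2}, \code{softmax}); defaults follow the variant.
#' @param n_classes Number of output classes (softmax width), default 2.
#' @param gru_hidden Hidden channels of the ConvGRU layer, default 8.
#' @param kernel Convolution kernel size, default 3.
#' @return An object of class \code{dccnn_arch}.
#' @export
dc_architecture <- function(variant = c("classbias_dccnn", "scanner_dccnn",
                                        "fe_model", "fe_dccnn",
                                        "convgru_dccnn", "custom"),
                            input_shape = c(66, 66),
                            conv_filters = NULL, fc_sizes = NULL,
                            dropout = NULL, taps = NULL, n_classes = 2L,
                            gru_hidden = 8L, kernel = 3L) {
  variant <- match.arg(variant)
  def <- switch(variant,
    classbias_dccnn = list(conv = c(32L, 64L, 128L), fc = c(64L, 32L),
                           drop = 0, taps = c("fc1", "fc2", "softmax")),
    scanner_dccnn = list(conv = c(32L, 16L, 16L), fc = c(40L, 100L),
                         drop = 0, taps = c("conv1", "fc1", "fc2")),
    fe_model = list(conv = c(32L, 16L, 16L, 8L, 8L), fc = c(40L, 100L),
                    drop = 0.2, taps = "conv5"),
    fe_dccnn = list(conv = c(32L, 16L, 16L, 8L, 8L), fc = c(40L, 100L),
                    drop = 0.2, taps = c("conv5", "fc1", "fc2")),
    convgru_dccnn = list(conv = c(16L, 32L, 32L), fc = c(1000L, 500L),
                         drop = 0, taps = c("conv2", "fc1")),
    custom = list(conv = NULL, fc = NULL, drop = 0, taps = NULL))
  conv_filters <- if (is.null(conv_filters)) def$conv else as.integer(conv_filters)
  fc_sizes <- if (is.null(fc_sizes)) def$fc else as.integer(fc_sizes)
  dropout <- if (is.null(dropout)) def$drop else dropout
  taps <- if (is.null(taps)) def$taps else taps
  if (is.null(conv_filters) || is.null(fc_sizes)) {
    stop("custom architectures need conv_filters and fc_sizes")
  }
  if (is.null(taps)) taps <- c("fc1", "fc2")
  temporal <- variant == "convgru_dccnn"
  if (temporal && length(input_shape) != 3L) {
    stop("convgru_dccnn needs input_shape = c(T, H, W)")
  }
  if (!temporal && length(input_shape) != 2L) {
    stop("2D variants need input_shape = c(H, W)")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(variant = variant, input_shape = as.integer(input_shape),
                 conv_filters = conv_filters, fc_sizes = fc_sizes,
                 dropout = dropout, taps = taps, n_classes = as.integer(n_classes),
                 gru_hidden = as.integer(gru_hidden), kernel = as.integer(kernel),
                 temporal = temporal),
            class = "dccnn_arch")
}

#' @export
print.dccnn_arch <- function(x, ...) {
  cat("DcCNN architecture:", x$variant, "\n")
  cat("  input:", paste(x$input_shape, collapse = " x "),
      if (x$temporal) "(T x H x W)" else "(H x W)", "\n")
  if (x$temporal) cat("  convGRU hidden channels:", x$gru_hidden, "\n")
  cat("  conv filters:", paste(x$conv_filters, collapse = ", "),
      " fc:", paste(x$fc_sizes, collapse = ", "), "\n")
  cat("  taps:", paste(x$taps, collapse = ", "),
      " dropout:", x$dropout, "\n")
  invisible(x)
}

#' Build a network from an architecture specification
#'
#' Instantiates layers with He-initialized weights. The returned network
#' records a tap table mapping tap names to layer outputs; conv taps refer to
#' the full conv block output (after activation, normalization and pooling).
#'
#' @param arch A [dc_architecture()] object.
#' @param seed Integer seed for the weight initialization.
#' @return An object of class \code{dccnn_net}.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "dccnn_arch"))
  set.seed(seed)
  layers <- list()
  taps <- integer(0)
  if (arch$temporal) {
    h <- arch$input_shape[2]; w <- arch$input_shape[3]
    gp <- convgru_params(arch$gru_hidden, h, w, arch$kernel)
    layers[[1]] <- list(type = "convgru", params = gp,
                        out_shape = c(h, w, arch$gru_hidden))
    shape <- c(h, w, arch$gru_hidden)
  } else {
    shape <- c(arch$input_shape, 1L)
  }
  for (i in seq_along(arch$conv_filters)) {
    layers[[length(layers) + 1L]] <- layer_conv(shape, arch$conv_filters[i],
                                                arch$kernel)
    shape <- layers[[length(layers)]]$out_shape
    layers[[length(layers) + 1L]] <- layer_relu(shape)
    layers[[length(layers) + 1L]] <- layer_bnorm(shape)
    if (arch$dropout > 0 && i <= 4L) {
      layers[[length(layers) + 1L]] <- layer_dropout(shape, arch$dropout)
    }
    if (shape[1] >= 2L && shape[2] >= 2L) {
      layers[[length(layers) + 1L]] <- layer_pool(shape)
      shape <- layers[[length(layers)]]$out_shape
    }
    taps[paste0("conv", i)] <- length(layers)
  }
  layers[[length(layers) + 1L]] <- layer_flatten(shape)
  din <- prod(shape)
  for (j in seq_along(arch$fc_sizes)) {
    layers[[length(layers) + 1L]] <- layer_dense(din, arch$fc_sizes[j], "relu")
    din <- arch$fc_sizes[j]
    taps[paste0("fc", j)] <- length(layers)
  }
  layers[[length(layers) + 1L]] <- layer_dense(din, arch$n_classes, "softmax")
  taps["softmax"] <- length(layers)
  missing_taps <- setdiff(arch$taps, names(taps))
  if (length(missing_taps)) {
    stop("tap(s) not present in this architecture: ",
         paste(missing_taps, collapse = ", "))
  }
  structure(list(layers = layers, taps = taps, arch = arch, seed = seed),
            class = "dccnn_net")
}

# Coerce image stacks to the engine's batch layout: (H, W, N, 1) for 2D
# models, (H, W, T, N) (single channel) for the temporal variant.
as_batch <- function(x, temporal = FALSE) {
  d <- dim(x)
  if (temporal) {
    if (length(d) == 3L) dim(x) <- c(d, 1L)
    x
  } else {
    if (length(d) == 2L) d <- c(d, 1L)
    dim(x) <- c(d[1], d[2], d[3], 1L)
    x
  }
}

#' Extract concatenated tap features
#'
#' Runs the network in inference mode and returns the flattened, concatenated
#' activations of the requested taps: the feature matrix F of the
#' decorrelation penalty, one row per sample.
#'
#' @param model A \code{dccnn_net} or fitted \code{dccnn} object.
#' @param x Image stack \code{(H, W, N)}, or \code{(H, W, T, N)} for the
#'   temporal variant.
#' @param taps Tap names; defaults to the architecture's tap set.
#' @return Numeric matrix, N rows.
#' @export
extract_features <- function(model, x, taps = NULL) {
  net <- if (inherits(model, "dccnn")) model$net else model
  if (is.null(taps)) taps <- net$arch$taps
  if (!length(taps)) stop("empty tap set")
  bad <- setdiff(taps, names(net$taps))
  if (length(bad)) stop("unknown tap(s): ", paste(bad, collapse = ", "))
  fw <- net_forward(net, as_batch(x, net$arch$temporal), training = FALSE)
  gather_taps(fw, net$taps[taps])
}

# Flatten and cbind tap outputs from a forward pass; tap order is fixed.
gather_taps <- function(fw, tap_idx) {
  mats <- lapply(tap_idx, function(i) {
    o <- fw$outs[[i]]
    if (is.matrix(o)) o else flatten_spatial(o)
  })
  do.call(cbind, mats)
}

# Predicted class probabilities from a raw network.
net_predict <- function(net, x) {
  net_forward(net, as_batch(x, net$arch$temporal), training = FALSE)$out
}
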