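# Minimal dense/convolutional network engine with manual backpropagation.
#
# Layout conventions (chosen so every im2col reshape is a free `dim<-`):
#   conv activations: array (H, W, N, C)   — N = batch size, C = channels
#   dense activations: matrix (N, D)
# Convolutions are k x k (default 3), stride 1, zero 'same' padding, computed
# as one big gather followed by one BLAS product; max pooling is 2x2 stride 2
# (floor). All randomness is drawn from the caller's RNG stream.

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# --- convolution ----------------------------------------------------------

# Static geometry for a k x k stride-1 'same' convolution on (h, w) inputs
# with c channels: the within-sample im2col index, the spatially flipped
# kernel order for the transposed-convolution input gradient, and a
# batch-size-keyed cache (held in an environment so it is shared by
# reference across network copies) of the full gather index.
conv_geom <- function(h, w, c, k) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  oh <- rep(seq_len(h), times = w)            # output positions, h fastest
  ow <- rep(seq_len(w), each = h)
  off <- expand.grid(dh = 0:(k - 1L), dw = 0:(k - 1L))
  spat <- matrix(0L, h * w, k * k)
  for (j in seq_len(k * k)) {
    spat[, j] <- (oh + off$dh[j]) + (ow + off$dw[j] - 1L) * hp
  }
  e <- new.env(parent = emptyenv())
  e$spat <- spat; e$k2 <- k * k; e$c <- c
  e$pad <- p; e$hp <- hp; e$wp <- wp; e$h <- h; e$w <- w; e$P <- h * w
  e$flip <- (k - 1L - off$dh) + (k - 1L - off$dw) * k + 1L
  e$full <- list()
  e
}

im2col_full_index <- function(im, n) {
  key <- as.character(n)
  f <- im$full[[key]]
  if (!is.null(f)) return(f)
  hw <- im$hp * im$wp
  K <- im$k2 * im$c; P <- im$P
  m1 <- t(im$spat)[rep(seq_len(im$k2), times = im$c), , drop = FALSE] +
    rep((seq_len(im$c) - 1L) * hw * n, each = im$k2)
  f <- rep(as.vector(m1), times = n) + rep((seq_len(n) - 1L) * hw, each = K * P)
  if (length(im$full) < 4L) im$full[[key]] <- f
  f
}

pad_input <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  xp
}

# x: (H, W, N, Cin); wm: (k*k*Cin, Cout) with rows ordered (dh, dw, ch).
conv_forward <- function(x, wm, b, im, keep_xg = TRUE) {
  d <- dim(x); n <- d[3]
  xp <- pad_input(x, im$pad)
  K <- im$k2 * im$c
  xg <- xp[im2col_full_index(im, n)]
  dim(xg) <- c(K, im$P * n)
  y <- crossprod(xg, wm)                      # (P*N, Cout)
  for (co in seq_along(b)) if (b[co] != 0) y[, co] <- y[, co] + b[co]
  dim(y) <- c(im$h, im$w, n, ncol(wm))
  list(out = y, xg = if (keep_xg) xg else NULL, in_dim = d)
}

# Stride-1 'same' convolution: the input gradient equals a 'same' convolution
# of dout with the spatially flipped, channel-transposed kernel, computed as
# one more gather + GEMM through `im_bwd` (the geometry built for Cout
# channels).
conv_backward <- function(dout, cache, wm, im, im_bwd = NULL, need_dx = TRUE) {
  d <- cache$in_dim; n <- d[3]
  cout <- ncol(wm)
  dy <- dout
  dim(dy) <- c(im$P * n, cout)
  dwm <- cache$xg %*% dy
  db <- colSums(dy)
  dx <- NULL
  if (need_dx) {
    wf <- matrix(0, im$k2 * cout, im$c)
    for (ci in seq_len(im$c)) {
      wf[, ci] <- as.vector(wm[im$flip + (ci - 1L) * im$k2, , drop = FALSE])
    }
    dim(dy) <- c(im$h, im$w, n, cout)
    dx <- conv_forward(dy, wf, numeric(im$c), im_bwd, keep_xg = FALSE)$out
  }
  list(dx = dx, dW = dwm, db = db)
}

# --- pooling, batch norm, activations -------------------------------------

pool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  i1 <- seq_len(h2) * 2L - 1L; j1 <- seq_len(w2) * 2L - 1L
  x11 <- x[i1, j1, , , drop = FALSE]
  x21 <- x[i1 + 1L, j1, , , drop = FALSE]
  x12 <- x[i1, j1 + 1L, , , drop = FALSE]
  x22 <- x[i1 + 1L, j1 + 1L, , , drop = FALSE]
  out <- pmax(x11, x21, x12, x22)
  list(out = out, parts = list(x11, x21, x12, x22), in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  i1 <- seq_len(h2) * 2L - 1L; j1 <- seq_len(w2) * 2L - 1L
  out <- pmax(cache$parts[[1]], cache$parts[[2]], cache$parts[[3]], cache$parts[[4]])
  dx <- array(0, d)
  taken <- array(FALSE, dim(dout))
  put <- list(list(i1, j1), list(i1 + 1L, j1), list(i1, j1 + 1L),
              list(i1 + 1L, j1 + 1L))
  for (q in 1:4) {
    m <- (cache$parts[[q]] == out) & !taken   # ties route to the first max
    taken <- taken | m
    dx[put[[q]][[1]], put[[q]][[2]], , ] <- dout * m
  }
  dx
}

# Per-channel batch normalization over (H, W, N).
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[4]
  xr <- x
  dim(xr) <- c(prod(d[1:3]), C)
  if (training) {
    M0 <- nrow(xr)
    m <- .colMeans(xr, M0, C)
    v <- .colMeans(xr * xr, M0, C) - m^2
    run_mean <- momentum * run_mean + (1 - momentum) * m
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    m <- run_mean; v <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- xr
  yr <- xr
  for (ch in seq_len(C)) {                     # column loops avoid sweep()'s
    xc <- (xr[, ch] - m[ch]) * ivar[ch]        # internal permutations
    xhat[, ch] <- xc
    yr[, ch] <- gamma[ch] * xc + beta[ch]
  }
  dim(yr) <- d
  list(out = yr, xhat = xhat, ivar = ivar, run_mean = run_mean,
       run_var = run_var, batch_mean = m, batch_var = v, in_dim = d)
}

# Re-estimate every batch-norm layer's inference statistics exactly, from
# forward passes over (a subsample of) the training data. Momentum-tracked
# running statistics lag badly when the learning rate is high relative to
# the number of iterations; checkpoints are recalibrated before any
# inference-mode evaluation.
calibrate_bn <- function(net, x_fetch, n_total, batch_size = 128L,
                         max_n = 512L) {
  bn_idx <- which(vapply(net$layers, function(l) l$type == "bnorm", TRUE))
  if (!length(bn_idx)) return(net)
  netq <- net     # dropout off: inference-consistent moments, no RNG draws
  for (i in seq_along(netq$layers)) {
    if (netq$layers[[i]]$type == "dropout") netq$layers[[i]]$rate <- 0
  }
  use <- if (n_total > max_n) {
    unique(round(seq(1L, n_total, length.out = max_n)))
  } else seq_len(n_total)
  acc <- lapply(bn_idx, function(i) list(s = 0, s2 = 0, n = 0))
  names(acc) <- as.character(bn_idx)
  for (start in seq(1L, length(use), by = batch_size)) {
    idx <- use[start:min(start + batch_size - 1L, length(use))]
    if (length(idx) < 2L) next
    fw <- net_forward(netq, x_fetch(idx), training = TRUE)
    for (i in bn_idx) {
      cc <- fw$caches[[i]]
      k <- as.character(i)
      nb <- prod(cc$in_dim[1:3])
      acc[[k]]$s <- acc[[k]]$s + nb * cc$batch_mean
      acc[[k]]$s2 <- acc[[k]]$s2 + nb * (cc$batch_var + cc$batch_mean^2)
      acc[[k]]$n <- acc[[k]]$n + nb
    }
  }
  for (i in bn_idx) {
    k <- as.character(i)
    if (acc[[k]]$n > 0) {
      m <- acc[[k]]$s / acc[[k]]$n
      net$layers[[i]]$run_mean <- m
      net$layers[[i]]$run_var <- pmax(acc[[k]]$s2 / acc[[k]]$n - m^2, 0)
    }
  }
  net
}

bn_backward <- function(dout, cache, gamma) {
  d <- cache$in_dim; C <- d[4]
  dr <- dout
  dim(dr) <- c(prod(d[1:3]), C)
  M <- nrow(dr)
  dgamma <- colSums(dr * cache$xhat)
  dbeta <- colSums(dr)
  dxr <- dr
  for (ch in seq_len(C)) {
    dxr[, ch] <- gamma[ch] * cache$ivar[ch] *
      (dr[, ch] - dbeta[ch] / M - cache$xhat[, ch] * (dgamma[ch] / M))
  }
  dim(dxr) <- d
  list(dx = dxr, dgamma = dgamma, dbeta = dbeta)
}

# --- layer constructors ----------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

layer_conv <- function(in_shape, filters, kernel = 3L) {
  k <- kernel
  cin <- in_shape[3]
  wm <- matrix(he_init(k * k * cin, k * k * cin * filters), k * k * cin, filters)
  list(type = "conv", W = wm, b = numeric(filters), kernel = k,
       im = conv_geom(in_shape[1], in_shape[2], cin, k),
       im_bwd = conv_geom(in_shape[1], in_shape[2], filters, k),
       out_shape = c(in_shape[1], in_shape[2], filters))
}

layer_bnorm <- function(in_shape) {
  C <- in_shape[3]
  list(type = "bnorm", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C), out_shape = in_shape)
}

layer_relu <- function(in_shape) list(type = "relu", out_shape = in_shape)

layer_pool <- function(in_shape) {
  list(type = "pool",
       out_shape = c(in_shape[1] %/% 2L, in_shape[2] %/% 2L, in_shape[3]))
}

layer_dropout <- function(in_shape, rate) {
  list(type = "dropout", rate = rate, out_shape = in_shape)
}

layer_flatten <- function(in_shape) {
  list(type = "flatten", out_shape = prod(in_shape))
}

layer_dense <- function(din, dout, activation = c("relu", "linear", "softmax")) {
  activation <- match.arg(activation)
  list(type = "dense", W = matrix(he_init(din, din * dout), din, dout),
       b = numeric(dout), activation = activation, out_shape = dout)
}

# (H, W, N, C) -> (N, H*W*C) with per-sample columns ordered (h, w, c)
flatten_spatial <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(y) <- c(d[1] * d[2] * d[4], d[3])
  t(y)
}

unflatten_spatial <- function(m, d) {
  y <- t(m)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  aperm(y, c(1L, 2L, 4L, 3L))
}

# --- ConvGRU ---------------------------------------------------------------

#' Initialize convolutional GRU parameters
#'
#' Gate weights for a convolutional gated recurrent unit: update, reset and
#' candidate gates, each a pair of 'same'-padded convolutions (input-to-hidden
#' and hidden-to-hidden) plus a bias map.
#'
#' @param hidden_channels Hidden-state channel count.
#' @param h,w Spatial size of the frames.
#' @param kernel Odd kernel size, default 3.
#' @return A parameter list consumed by [convgru_layer()].
#' @export
convgru_params <- function(hidden_channels, h, w, kernel = 3L) {
  k <- kernel
  mk <- function(cin) matrix(he_init(k * k * cin, k * k * cin * hidden_channels),
                             k * k * cin, hidden_channels)
  list(Wxz = mk(1L), Whz = mk(hidden_channels), bz = numeric(hidden_channels),
       Wxr = mk(1L), Whr = mk(hidden_channels), br = numeric(hidden_channels),
       Wxh = mk(1L), Whh = mk(hidden_channels), bh = numeric(hidden_channels),
       kernel = k, hidden_channels = hidden_channels,
       im_x = conv_geom(h, w, 1L, k),
       im_h = conv_geom(h, w, hidden_channels, k))
}

#' Convolutional GRU over a frame sequence
#'
#' Runs the gated recurrence
#' \deqn{z_t = \sigma(W_{xz} * x_t + W_{hz} * h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_{xr} * x_t + W_{hr} * h_{t-1} + b_r)}
#' \deqn{\tilde h_t = \tanh(W_{xh} * x_t + W_{hh} * (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#' (\eqn{*} a 'same' convolution) from a zero initial state and returns the
#' final hidden state, which summarizes the temporal stack into one spatial
#' feature map per hidden channel.
#'
#' @param x Single-channel frame sequences: array \code{(H, W, T, N)}, or
#'   \code{(H, W, T)} for one sequence.
#' @param params Parameters from [convgru_params()].
#' @param keep_cache Internal: retain per-step caches for backpropagation.
#' @return Array \code{(H, W, N, hidden)} (with \code{keep_cache = TRUE}, a
#'   list with fields \code{out} and \code{caches}).
#' @export
convgru_layer <- function(x, params, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L) stop("expected frames of shape (H, W, T, N)")
  Tn <- d[3]; n <- d[4]
  if (Tn < 1L) stop("need at least one frame")
  ch <- params$hidden_channels
  h <- array(0, c(d[1], d[2], n, ch))
  caches <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- x[, , t, , drop = FALSE]
    dim(xt) <- c(d[1], d[2], n, 1L)
    cz1 <- conv_forward(xt, params$Wxz, params$bz, params$im_x)
    cz2 <- conv_forward(h, params$Whz, numeric(ch), params$im_h)
    z <- nn_sigmoid(cz1$out + cz2$out)
    cr1 <- conv_forward(xt, params$Wxr, params$br, params$im_x)
    cr2 <- conv_forward(h, params$Whr, numeric(ch), params$im_h)
    r <- nn_sigmoid(cr1$out + cr2$out)
    rh <- r * h
    ch1 <- conv_forward(xt, params$Wxh, params$bh, params$im_x)
    ch2 <- conv_forward(rh, params$Whh, numeric(ch), params$im_h)
    hc <- tanh(ch1$out + ch2$out)
    hnew <- (1 - z) * h + z * hc
    if (keep_cache) {
      caches[[t]] <- list(h_prev = h, z = z, r = r, hc = hc,
                          cz1 = cz1, cz2 = cz2, cr1 = cr1, cr2 = cr2,
                          ch1 = ch1, ch2 = ch2)
    }
    h <- hnew
  }
  if (keep_cache) list(out = h, caches = caches) else h
}

convgru_backward <- function(dh, params, caches) {
  g <- list(Wxz = params$Wxz * 0, Whz = params$Whz * 0, bz = params$bz * 0,
            Wxr = params$Wxr * 0, Whr = params$Whr * 0, br = params$br * 0,
            Wxh = params$Wxh * 0, Whh = params$Whh * 0, bh = params$bh * 0)
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    dz <- dh * (cc$hc - cc$h_prev)
    dhc <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    dhc_pre <- dhc * (1 - cc$hc^2)
    b1 <- conv_backward(dhc_pre, cc$ch1, params$Wxh, params$im_x, need_dx = FALSE)
    b2 <- conv_backward(dhc_pre, cc$ch2, params$Whh, params$im_h, params$im_h,
                        need_dx = TRUE)
    g$Wxh <- g$Wxh + b1$dW; g$bh <- g$bh + b1$db
    g$Whh <- g$Whh + b2$dW
    drh <- b2$dx
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    bz1 <- conv_backward(dz_pre, cc$cz1, params$Wxz, params$im_x, need_dx = FALSE)
    bz2 <- conv_backward(dz_pre, cc$cz2, params$Whz, params$im_h, params$im_h,
                         need_dx = TRUE)
    g$Wxz <- g$Wxz + bz1$dW; g$bz <- g$bz + bz1$db
    g$Whz <- g$Whz + bz2$dW
    dh_prev <- dh_prev + bz2$dx
    dr_pre <- dr * cc$r * (1 - cc$r)
    br1 <- conv_backward(dr_pre, cc$cr1, params$Wxr, params$im_x, need_dx = FALSE)
    br2 <- conv_backward(dr_pre, cc$cr2, params$Whr, params$im_h, params$im_h,
                         need_dx = TRUE)
    g$Wxr <- g$Wxr + br1$dW; g$br <- g$br + br1$db
    g$Whr <- g$Whr + br2$dW
    dh_prev <- dh_prev + br2$dx
    dh <- dh_prev
  }
  g
}

# --- network forward / backward -------------------------------------------

# Forward pass through a layer list. Returns the final (N x n_classes)
# probability matrix, per-layer caches, and every layer's output (for taps).
net_forward <- function(net, x, training = FALSE) {
  layers <- net$layers
  caches <- vector("list", length(layers))
  outs <- vector("list", length(layers))
  cur <- x
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "convgru") {
      res <- convgru_layer(cur, ly$params, keep_cache = training)
      if (training) { caches[[i]] <- res$caches; cur <- res$out } else cur <- res
    } else if (ly$type == "conv") {
      res <- conv_forward(cur, ly$W, ly$b, ly$im)
      caches[[i]] <- res; cur <- res$out
    } else if (ly$type == "bnorm") {
      res <- bn_forward(cur, ly$gamma, ly$beta, ly$run_mean, ly$run_var, training)
      caches[[i]] <- res; cur <- res$out
      if (training) {
        net$layers[[i]]$run_mean <- res$run_mean
        net$layers[[i]]$run_var <- res$run_var
      }
    } else if (ly$type == "relu") {
      mask <- cur > 0
      caches[[i]] <- list(mask = mask); cur <- cur * mask
    } else if (ly$type == "pool") {
      res <- pool_forward(cur); caches[[i]] <- res; cur <- res$out
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(cur)) >= ly$rate) / (1 - ly$rate)
        dim(mask) <- dim(cur)
        caches[[i]] <- list(mask = mask); cur <- cur * mask
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(cur))
      cur <- flatten_spatial(cur)
    } else if (ly$type == "dense") {
      z <- cur %*% ly$W
      for (co in seq_along(ly$b)) if (ly$b[co] != 0) z[, co] <- z[, co] + ly$b[co]
      out <- switch(ly$activation,
                    relu = pmax(z, 0),
                    linear = z,
                    softmax = {
                      e <- exp(z - apply(z, 1L, max)); e / rowSums(e)
                    })
      caches[[i]] <- list(x = cur, z = z, out = out)
      cur <- out
    } else stop("unknown layer type: ", ly$type)
    outs[[i]] <- cur
  }
  list(out = cur, caches = caches, outs = outs, net = net)
}

# Backward pass. `dout` is the gradient at the network output; `inject` is an
# optional list mapping layer index (as character) -> extra gradient added to
# that layer's output (used to feed the decorrelation penalty into tapped
# activations). Returns list(grads = per-layer parameter gradients).
net_backward <- function(net, fw, dout, inject = NULL) {
  layers <- net$layers
  grads <- vector("list", length(layers))
  cur <- dout
  for (i in rev(seq_along(layers))) {
    if (!is.null(inject) && !is.null(inject[[as.character(i)]])) {
      cur <- cur + inject[[as.character(i)]]
    }
    ly <- layers[[i]]
    cc <- fw$caches[[i]]
    if (ly$type == "dense") {
      dz <- switch(ly$activation,
                   relu = cur * (cc$z > 0),
                   linear = cur,
                   softmax = {
                     p <- cc$out
                     p * (cur - rowSums(cur * p))
                   })
      grads[[i]] <- list(W = crossprod(cc$x, dz), b = colSums(dz))
      cur <- tcrossprod(dz, ly$W)
    } else if (ly$type == "flatten") {
      cur <- unflatten_spatial(cur, cc$in_dim)
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) cur <- cur * cc$mask
    } else if (ly$type == "pool") {
      cur <- pool_backward(cur, cc)
    } else if (ly$type == "relu") {
      cur <- cur * cc$mask
    } else if (ly$type == "bnorm") {
      bb <- bn_backward(cur, cc, ly$gamma)
      grads[[i]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cur <- bb$dx
    } else if (ly$type == "conv") {
      bb <- conv_backward(cur, cc, ly$W, ly$im, ly$im_bwd, need_dx = (i > 1L))
      grads[[i]] <- list(W = bb$dW, b = bb$db)
      cur <- bb$dx
    } else if (ly$type == "convgru") {
      grads[[i]] <- list(params = convgru_backward(cur, ly$params, cc))
      cur <- NULL   # first layer by construction
    }
  }
  list(grads = grads)
}

#' Sum of squared trainable weights
#'
#' The L2 regularizer of the training objectives: the sum of squared
#' convolution and dense weights (and ConvGRU gate kernels). Bias vectors and
#' batch-normalization scale/shift parameters are excluded.
#'
#' @param net A built model (see [build_model()]) or a fitted `dccnn` object.
#' @return Nonnegative scalar.
#' @export
l2_penalty <- function(net) {
  if (inherits(net, "dccnn")) net <- net$net
  s <- 0
  for (ly in net$layers) {
    if (ly$type %in% c("conv", "dense")) s <- s + sum(ly$W^2)
    if (ly$type == "convgru") {
      for (nm in c("Wxz", "Whz", "Wxr", "Whr", "Wxh", "Whh")) {
        s <- s + sum(ly$params[[nm]]^2)
      }
    }
  }
  s
}

# L2 gradient contribution (2 * coeff * W) added to a grads list.
add_l2_grads <- function(net, grads, coeff) {
  if (coeff == 0) return(grads)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      if (is.null(grads[[i]])) grads[[i]] <- list(W = ly$W * 0, b = ly$b * 0)
      grads[[i]]$W <- grads[[i]]$W + 2 * coeff * ly$W
    } else if (ly$type == "convgru") {
      for (nm in c("Wxz", "Whz", "Wxr", "Whr", "Wxh", "Whh")) {
        grads[[i]]$params[[nm]] <- grads[[i]]$params[[nm]] + 2 * coeff * ly$params[[nm]]
      }
    }
  }
  grads
}

# --- optimizers ------------------------------------------------------------

opt_init <- function(net) {
  st <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      st[[i]] <- list(W = list(m = ly$W * 0, v = ly$W * 0),
                      b = list(m = ly$b * 0, v = ly$b * 0))
    } else if (ly$type == "bnorm") {
      st[[i]] <- list(gamma = list(m = ly$gamma * 0, v = ly$gamma * 0),
                      beta = list(m = ly$beta * 0, v = ly$beta * 0))
    } else if (ly$type == "convgru") {
      st[[i]] <- lapply(ly$params[c("Wxz", "Whz", "bz", "Wxr", "Whr", "br",
                                    "Wxh", "Whh", "bh")],
                        function(p) list(m = p * 0, v = p * 0))
    }
  }
  st
}

opt_update_one <- function(p, g, s, lr, optimizer, t, eps = 1e-8) {
  if (optimizer == "rmsprop") {
    s$v <- 0.9 * s$v + 0.1 * g^2
    p <- p - lr * g / (sqrt(s$v) + eps)
  } else {  # adam
    s$m <- 0.9 * s$m + 0.1 * g
    s$v <- 0.999 * s$v + 0.001 * g^2
    mh <- s$m / (1 - 0.9^t); vh <- s$v / (1 - 0.999^t)
    p <- p - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, s = s)
}

opt_step <- function(net, grads, state, lr, optimizer, t) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (is.null(grads[[i]])) next
    if (ly$type %in% c("conv", "dense")) {
      for (nm in c("W", "b")) {
        u <- opt_update_one(ly[[nm]], grads[[i]][[nm]], state[[i]][[nm]],
                            lr, optimizer, t)
        net$layers[[i]][[nm]] <- u$p; state[[i]][[nm]] <- u$s
      }
    } else if (ly$type == "bnorm") {
      for (nm in c("gamma", "beta")) {
        u <- opt_update_one(ly[[nm]], grads[[i]][[nm]], state[[i]][[nm]],
                            lr, optimizer, t)
        net$layers[[i]][[nm]] <- u$p; state[[i]][[nm]] <- u$s
      }
    } else if (ly$type == "convgru") {
      for (nm in names(grads[[i]]$params)) {
        u <- opt_update_one(ly$params[[nm]], grads[[i]]$params[[nm]],
                            state[[i]][[nm]], lr, optimizer, t)
        net$layers[[i]]$params[[nm]] <- u$p; state[[i]][[nm]] <- u$s
      }
    }
  }
  list(net = net, state = state)
}

net_param_count <- function(net) {
  s <- 0L
  for (ly in net$layers) {
    if (ly$type %in% c("conv", "dense")) s <- s + length(ly$W) + length(ly$b)
    if (ly$type == "bnorm") s <- s + length(ly$gamma) + length(ly$beta)
    if (ly$type == "convgru") {
      for (nm in c("Wxz", "Whz", "bz", "Wxr", "Whr", "br", "Wxh", "Whh", "bh")) {
        s <- s + length(ly$params[[nm]])
      }
    }
  }
  s
}
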