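# Standard MobileNetV2 building blocks plus the efficient channel attention
# (ECA) module.

#' Depthwise-separable convolution cost ratio
#'
#' Ratio of the multiply-accumulate cost of a depthwise-separable
#' convolution (per-channel K x K pass followed by a 1 x 1 channel-mixing
#' pass) to the cost of the equivalent standard convolution:
#' `1/N + 1/K^2`, where `K` is the kernel side and `N` the number of output
#' channels.  For K = 3 and large N the factorized form needs about one
#' ninth of the standard cost.
#'
#' @param K Kernel side (>= 1).
#' @param N Number of output channels (>= 1; `Inf` gives the large-N limit).
#' @return The cost ratio as a double.
#' @export
cost_ratio <- function(K, N) {
  if (K < 1 || N < 1) stop("K and N must be positive")
  1 / N + 1 / K^2
}

#' Depthwise-separable convolution forward pass
#'
#' Applies a depthwise (per-channel) spatial convolution followed by a
#' pointwise 1 x 1 channel-fusion convolution.
#'
#' @param x Feature map `(N, C, H, W)`.
#' @param dw Depthwise conv layer (`groups == in_channels`).
#' @param pw Pointwise conv layer (`kernel_size == 1`).
#' @return Feature map with `pw$out_channels` channels.
#' @export
depthwise_separable_forward <- function(x, dw, pw) {
  if (dw$groups != dw$in_channels || dw$in_channels != dw$out_channels)
    stop("dw must be depthwise: groups == in_channels == out_channels")
  if (pw$kernel_size != 1) stop("pw must be a 1 x 1 convolution")
  if (fm_dims(x)[2] != dw$in_channels || pw$in_channels != dw$out_channels)
    stop("channel mismatch between x, dw and pw")
  mid <- layer_forward(dw, x)$out
  layer_forward(pw, mid)$out
}

## ---- ECA --------------------------------------------------------------

#' Channel-adaptive ECA kernel size
#'
#' Maps a channel count to the length of the 1-D cross-channel convolution
#' used by the efficient channel attention module:
#' `k = |log2(C)/gamma + b/gamma|`, rounded down and then bumped to the
#' nearest odd integer at least that large, so layers with more channels
#' interact across a wider neighbourhood.
#'
#' @param C Channel count (>= 1).
#' @param gamma,b Coefficients of the kernel-size map.
#' @return Odd integer kernel size.
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (C < 1) stop("C must be >= 1")
  t <- floor(abs(log2(C) / gamma + b / gamma))
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(1, k))
}

#' Efficient channel attention (ECA) layer
#'
#' Global average pooling over space, a 1-D convolution across the channel
#' vector (kernel size adapted to the channel count), a sigmoid gate, and a
#' per-channel rescaling of the input.  Adds only `k` parameters.
#'
#' @param channels Channel count of the gated feature map.
#' @param k Kernel size; default picked by [eca_kernel_size()].
#' @param gamma,b Passed to [eca_kernel_size()] when `k` is missing.
#' @return An ECA layer.
#' @export
nn_eca <- function(channels, k = NULL, gamma = 2, b = 1) {
  if (is.null(k)) k <- eca_kernel_size(channels, gamma, b)
  if (k %% 2 != 1 || k < 1) stop("ECA kernel must be a positive odd integer")
  if (k > channels) stop("ECA kernel longer than the channel vector")
  new_layer("eca", list(channels = channels, k = as.integer(k),
                        weight = rnorm(k, sd = 0.1)))
}

# 1-D cross-channel convolution with zero padding, shared filter.
eca_conv1d <- function(v, w) {
  k <- length(w)
  half <- (k - 1) / 2
  C <- ncol(v)
  out <- matrix(0, nrow(v), C)
  for (j in seq_len(k)) {
    off <- j - 1 - half
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    out[, ok] <- out[, ok] + w[j] * v[, src[ok], drop = FALSE]
  }
  out
}

#' @export
layer_forward.nn_eca <- function(layer, x, training = FALSE) {
  d <- fm_dims(x)
  if (d[2] != layer$channels) stop("ECA: channel mismatch")
  v <- global_pool_forward(x)            # (N, C)
  pre <- eca_conv1d(v, layer$weight)
  s <- sigmoid(pre)
  gate <- array(rep(as.numeric(s), times = d[3] * d[4]), d)
  list(out = x * gate,
       cache = list(x = x, v = v, s = s, dims = d))
}

#' @export
layer_backward.nn_eca <- function(layer, cache, gout) {
  d <- cache$dims
  s <- cache$s
  gate <- array(rep(as.numeric(s), times = d[3] * d[4]), d)
  gx_direct <- gout * gate
  # gradient into the per-channel gate
  gs <- matrix(rowSums(matrix(gout * cache$x, nrow = d[1] * d[2])),
               d[1], d[2])
  gpre <- gs * s * (1 - s)
  # conv1d backward: weight grad and input grad (correlation transpose)
  k <- layer$k
  half <- (k - 1) / 2
  C <- d[2]
  gw <- numeric(k)
  gv <- matrix(0, d[1], C)
  for (j in seq_len(k)) {
    off <- j - 1 - half
    src <- seq_len(C) + off
    ok <- src >= 1 & src <= C
    gw[j] <- sum(gpre[, ok, drop = FALSE] * cache$v[, src[ok], drop = FALSE])
    gv[, src[ok]] <- gv[, src[ok], drop = FALSE] + layer$weight[j] * gpre[, ok, drop = FALSE]
  }
  gx_pool <- global_pool_backward(gv, d)
  list(gin = gx_direct + gx_pool, grads = list(weight = gw))
}

#' @export
layer_params.nn_eca <- function(layer) list(weight = layer$weight)

#' @export
layer_set_params.nn_eca <- function(layer, params) {
  layer$weight <- as.numeric(params$weight)
  layer
}

#' ECA forward pass on a feature map
#'
#' Functional wrapper around the ECA layer: gates each channel of `x` by
#' the sigmoid of a 1-D cross-channel convolution of the spatially pooled
#' channel vector.
#'
#' @param x Feature map `(N, C, H, W)`.
#' @param weight Numeric vector of odd length `k <= C` (the shared 1-D
#'   filter).
#' @return Feature map, same shape as `x`.
#' @export
eca_forward <- function(x, weight) {
  l <- nn_eca(fm_dims(x)[2], k = length(weight))
  l$weight <- as.numeric(weight)
  layer_forward(l, x)$out
}

## ---- inverted residual ------------------------------------------------

#' Inverted residual block (MobileNetV2 bottleneck)
#'
#' Expands channels by `expand_t` with a 1 x 1 convolution, filters with a
#' 3 x 3 depthwise convolution (stride `s`), then linearly projects back
#' down with a second 1 x 1 convolution.  No activation follows the
#' projection; a skip connection is added when `stride == 1` and the
#' channel count is preserved.
#'
#' @param in_channels,out_channels Channel counts.
#' @param expand_t Expansion multiplier (>= 1); `t = 1` omits the expansion
#'   convolution.
#' @param stride 1 or 2 (on the depthwise convolution).
#' @param activation Activation after the first two convolutions.
#' @return An inverted-residual block layer.
#' @export
nn_inverted_residual <- function(in_channels, out_channels, expand_t = 6,
                                 stride = 1L, activation = "relu6") {
  stopifnot(expand_t >= 1, stride %in% c(1L, 2L))
  hidden <- as.integer(round(in_channels * expand_t))
  layers <- list()
  if (expand_t != 1) {
    layers$expand_conv <- nn_conv2d(in_channels, hidden, 1)
    layers$expand_bn <- nn_batchnorm2d(hidden)
    layers$expand_act <- nn_activation(activation)
  }
  layers$dw_conv <- nn_conv2d(hidden, hidden, 3, stride = stride, padding = 1,
                              groups = hidden)
  layers$dw_bn <- nn_batchnorm2d(hidden)
  layers$dw_act <- nn_activation(activation)
  layers$proj_conv <- nn_conv2d(hidden, out_channels, 1)
  layers$proj_bn <- nn_batchnorm2d(out_channels)
  new_layer("inverted_residual", list(
    in_channels = in_channels, out_channels = out_channels,
    expand_t = expand_t, stride = as.integer(stride),
    use_residual = stride == 1L && in_channels == out_channels,
    layers = layers))
}

#' @export
layer_forward.nn_inverted_residual <- function(layer, x, training = FALSE) {
  body <- nn_sequential(layer$layers)
  r <- layer_forward(body, x, training)
  out <- if (layer$use_residual) r$out + x else r$out
  list(out = out, cache = r$cache)
}

#' @export
layer_backward.nn_inverted_residual <- function(layer, cache, gout) {
  body <- nn_sequential(layer$layers)
  r <- layer_backward(body, cache, gout)
  gin <- if (layer$use_residual) r$gin + gout else r$gin
  list(gin = gin, grads = r$grads)
}

#' Inverted residual forward pass
#'
#' Functional form of the block: see [nn_inverted_residual()].
#'
#' @param x Feature map.
#' @param block An inverted-residual block layer.
#' @param training Batch-norm mode.
#' @return Output feature map.
#' @export
inverted_residual_forward <- function(x, block, training = FALSE) {
  layer_forward(block, x, training)$out
}
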