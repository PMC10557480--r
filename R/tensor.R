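# Feature maps are plain R arrays with dim = c(N, C, H, W): batch, channels,
# height, width.  All blocks consume and produce this layout.

#' Create a feature map array
#'
#' Convenience constructor for the 4-D batch x channels x height x width
#' arrays that every block in the package consumes and produces.
#'
#' @param values Numeric vector or array of length `prod(dim)`.
#' @param dim Integer vector `c(N, C, H, W)`.
#' @return A numeric array with class-free NCHW layout.
#' @export
feature_map <- function(values, dim) {
  stopifnot(length(dim) == 4L, all(dim >= 1L))
  x <- array(as.numeric(values), dim = as.integer(dim))
  if (!all(is.finite(x))) stop("feature map entries must be finite")
  x
}

fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a 4-D (N, C, H, W) array")
  d
}

#' Grouped 2-D convolution forward pass
#'
#' Direct NCHW convolution with stride, zero padding and channel groups.
#' Depthwise convolution is the `groups = in_channels` case; pointwise
#' (1 x 1) convolution is `kernel = 1`.
#'
#' @param x Feature map `(N, C_in, H, W)`.
#' @param weight Array `(C_out, C_in/groups, K, K)`.
#' @param bias Optional numeric vector of length `C_out`, or `NULL`.
#' @param stride,padding,groups Convolution hyper-parameters.
#' @return Feature map `(N, C_out, H', W')`.
#' @export
conv2d_forward <- function(x, weight, bias = NULL, stride = 1L, padding = 0L,
                           groups = 1L) {
  xd <- fm_dims(x)
  wd <- dim(weight)
  if (length(wd) != 4L) stop("weight must be (C_out, C_in/groups, K, K)")
  if (xd[2] %% groups != 0 || wd[1] %% groups != 0)
    stop("channel counts must be divisible by groups")
  if (wd[2] != xd[2] / groups)
    stop("channel mismatch between input and weight")
  cpp_conv2d_forward(as.numeric(x), as.integer(xd),
                     as.numeric(weight), as.integer(wd),
                     if (is.null(bias)) numeric(0) else as.numeric(bias),
                     as.integer(stride), as.integer(padding), as.integer(groups))
}

conv2d_backward <- function(x, weight, grad_out, stride = 1L, padding = 0L,
                            groups = 1L, has_bias = FALSE) {
  cpp_conv2d_backward(as.numeric(x), as.integer(fm_dims(x)),
                      as.numeric(weight), as.integer(dim(weight)),
                      as.numeric(grad_out),
                      as.integer(stride), as.integer(padding),
                      as.integer(groups), isTRUE(has_bias))
}

# 2x2 stride-2 average pooling (the parameter-free downsample used when an
# FC-partitioned stage must halve resolution).
avgpool2x2_forward <- function(x) {
  d <- fm_dims(x)
  if (d[3] %% 2 != 0 || d[4] %% 2 != 0) stop("avgpool2x2 needs even H and W")
  ho <- d[3] / 2; wo <- d[4] / 2
  (x[, , seq(1, d[3], 2), seq(1, d[4], 2), drop = FALSE] +
   x[, , seq(2, d[3], 2), seq(1, d[4], 2), drop = FALSE] +
   x[, , seq(1, d[3], 2), seq(2, d[4], 2), drop = FALSE] +
   x[, , seq(2, d[3], 2), seq(2, d[4], 2), drop = FALSE]) / 4
}

avgpool2x2_backward <- function(grad_out, in_dim) {
  g <- array(0, in_dim)
  go <- grad_out / 4
  g[, , seq(1, in_dim[3], 2), seq(1, in_dim[4], 2)] <- go
  g[, , seq(2, in_dim[3], 2), seq(1, in_dim[4], 2)] <- go
  g[, , seq(1, in_dim[3], 2), seq(2, in_dim[4], 2)] <- go
  g[, , seq(2, in_dim[3], 2), seq(2, in_dim[4], 2)] <- go
  g
}

# Global average pooling (N,C,H,W) -> (N,C) matrix.
global_pool_forward <- function(x) {
  d <- fm_dims(x)
  m <- rowMeans(matrix(x, nrow = d[1] * d[2]))
  matrix(m, nrow = d[1], ncol = d[2])
}

global_pool_backward <- function(grad_out, in_dim) {
  array(rep(as.numeric(grad_out) / (in_dim[3] * in_dim[4]),
            times = in_dim[3] * in_dim[4]), in_dim)
}
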