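#' ReLU6 activation
#'
#' `min(max(x, 0), 6)`, the clipped rectifier used throughout MobileNetV2's
#' standard bottlenecks.
#'
#' @param x Numeric vector or array.
#' @return Same shape as `x`.
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' Hardswish activation
#'
#' `x * min(max(x + 3, 0), 6) / 6`, a piecewise-polynomial approximation of
#' swish.  Used in place of ReLU6 inside the improved bottleneck blocks,
#' where its smooth, non-monotonic profile helps deeper models.
#'
#' @param x Numeric vector or array.
#' @return Same shape as `x`.
#' @export
hardswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

relu <- function(x) pmax(x, 0)

activation_forward <- function(kind, x) {
  switch(kind,
         relu6 = relu6(x),
         hardswish = hardswish(x),
         relu = relu(x),
         identity = x,
         stop("unknown activation: ", kind))
}

activation_grad <- function(kind, x) {
  switch(kind,
         relu6 = (x > 0 & x < 6) * 1,
         hardswish = ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6)),
         relu = (x > 0) * 1,
         identity = array(1, dim(x) %||% length(x)),
         stop("unknown activation: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))
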