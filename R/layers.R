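# Minimal layer system.  A layer is a list with class c("nn_<kind>",
# "nn_layer").  Four generics cover everything the package needs:
#   layer_forward(layer, x, training)  -> list(out, cache)
#   layer_backward(layer, cache, gout) -> list(gin, grads)   (grads mirrors
#                                         layer_params() naming)
#   layer_params(layer)                -> nested named list of trainable arrays
#   layer_set_params(layer, params)    -> layer with new values
# Composite layers hold children in $layers and recurse.  Batch-norm running
# statistics live in an environment so training-mode forward can update them
# in place; they are buffers, not trainable parameters.

#' Layer forward pass
#' @param layer A layer object.
#' @param x Input feature map or matrix.
#' @param training Logical; batch-norm layers use batch statistics (and
#'   update running statistics) when `TRUE`, running statistics otherwise.
#' @return List with elements `out` and `cache` (the latter feeds
#'   [layer_backward()]).
#' @export
layer_forward <- function(layer, x, training = FALSE) UseMethod("layer_forward")

#' Layer backward pass
#' @param layer A layer object.
#' @param cache Cache returned by [layer_forward()].
#' @param gout Gradient of the loss with respect to the layer output.
#' @return List with `gin` (gradient w.r.t. input) and `grads` (named like
#'   [layer_params()]).
#' @export
layer_backward <- function(layer, cache, gout) UseMethod("layer_backward")

#' Trainable parameters of a layer
#' @param layer A layer object.
#' @return Nested named list of numeric arrays.
#' @export
layer_params <- function(layer) UseMethod("layer_params")

#' Replace trainable parameters of a layer
#' @param layer A layer object.
#' @param params Nested list as returned by [layer_params()].
#' @return The layer with new parameter values.
#' @export
layer_set_params <- function(layer, params) UseMethod("layer_set_params")

new_layer <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = c(paste0("nn_", kind), "nn_layer"))
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

## ---- conv2d -----------------------------------------------------------

#' 2-D convolution layer
#'
#' @param in_channels,out_channels Channel counts; both must be divisible by
#'   `groups`.
#' @param kernel_size Square kernel side K.
#' @param stride,padding,groups Convolution hyper-parameters.
#' @param bias Include a bias vector?  Convolutions followed by batch norm
#'   conventionally omit it.
#' @param init `"kaiming"` (default) or `"zero"`.
#' @return A conv layer.
#' @export
nn_conv2d <- function(in_channels, out_channels, kernel_size, stride = 1L,
                      padding = 0L, groups = 1L, bias = FALSE,
                      init = "kaiming") {
  stopifnot(kernel_size >= 1, stride >= 1, padding >= 0,
            in_channels %% groups == 0, out_channels %% groups == 0)
  wd <- c(out_channels, in_channels / groups, kernel_size, kernel_size)
  fan_in <- (in_channels / groups) * kernel_size^2
  w <- if (init == "zero") array(0, wd) else kaiming_uniform(wd, fan_in)
  new_layer("conv2d", list(
    in_channels = in_channels, out_channels = out_channels,
    kernel_size = kernel_size, stride = as.integer(stride),
    padding = as.integer(padding), groups = as.integer(groups),
    weight = w, bias = if (bias) numeric(out_channels) else NULL))
}

#' @export
layer_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  if (fm_dims(x)[2] != layer$in_channels)
    stop("conv2d: input has ", fm_dims(x)[2], " channels, expected ",
         layer$in_channels)
  out <- conv2d_forward(x, layer$weight, layer$bias, layer$stride,
                        layer$padding, layer$groups)
  list(out = out, cache = list(x = x))
}

#' @export
layer_backward.nn_conv2d <- function(layer, cache, gout) {
  r <- conv2d_backward(cache$x, layer$weight, gout, layer$stride,
                       layer$padding, layer$groups, !is.null(layer$bias))
  grads <- list(weight = r$gw)
  if (!is.null(layer$bias)) grads$bias <- r$gb
  list(gin = r$gx, grads = grads)
}

#' @export
layer_params.nn_conv2d <- function(layer) {
  p <- list(weight = layer$weight)
  if (!is.null(layer$bias)) p$bias <- layer$bias
  p
}

#' @export
layer_set_params.nn_conv2d <- function(layer, params) {
  layer$weight <- array(params$weight, dim(layer$weight))
  if (!is.null(layer$bias)) layer$bias <- as.numeric(params$bias)
  layer
}

## ---- batch norm -------------------------------------------------------

#' 2-D batch normalization layer
#'
#' Normalizes each channel over (batch, height, width).  Inference uses the
#' running statistics; training mode uses batch statistics and updates the
#' running buffers in place (they live in an environment, so updates survive
#' R's copy-on-modify).
#'
#' @param channels Number of channels.
#' @param eps Variance floor added before the square root.
#' @param momentum Running-statistics update rate.
#' @return A batch-norm layer.
#' @export
nn_batchnorm2d <- function(channels, eps = 1e-5, momentum = 0.1) {
  stats_env <- new.env(parent = emptyenv())
  stats_env$mean <- numeric(channels)
  stats_env$var <- rep(1, channels)
  new_layer("batchnorm2d", list(
    channels = channels, eps = eps, momentum = momentum,
    gamma = rep(1, channels), beta = numeric(channels), stats = stats_env))
}

#' @export
layer_forward.nn_batchnorm2d <- function(layer, x, training = FALSE) {
  d <- fm_dims(x)
  C <- layer$channels
  if (d[2] != C) stop("batchnorm: channel mismatch")
  xp <- aperm(x, c(1, 3, 4, 2))             # (N,H,W,C)
  xm <- matrix(xp, ncol = C)                # rows = (n,h,w), cols = channel
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2              # biased batch variance
    n_el <- nrow(xm)
    layer$stats$mean <- (1 - layer$momentum) * layer$stats$mean + layer$momentum * mu
    unb <- if (n_el > 1) v * n_el / (n_el - 1) else v
    layer$stats$var <- (1 - layer$momentum) * layer$stats$var + layer$momentum * unb
  } else {
    mu <- layer$stats$mean
    v <- layer$stats$var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  ym <- sweep(xhat, 2, layer$gamma, "*")
  ym <- sweep(ym, 2, layer$beta, "+")
  out <- aperm(array(ym, dim(xp)), c(1, 4, 2, 3))
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training))
}

#' @export
layer_backward.nn_batchnorm2d <- function(layer, cache, gout) {
  d <- cache$dims
  C <- layer$channels
  gm <- matrix(aperm(gout, c(1, 3, 4, 2)), ncol = C)
  xhat <- cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  gxhat <- sweep(gm, 2, layer$gamma, "*")
  if (cache$training) {
    n_el <- nrow(gm)
    t1 <- sweep(gxhat, 2, colMeans(gxhat), "-")
    t2 <- sweep(xhat, 2, colMeans(gxhat * xhat), "*")
    gxm <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    gxm <- sweep(gxhat, 2, cache$invstd, "*")
  }
  gin <- aperm(array(gxm, c(d[1], d[3], d[4], C)), c(1, 4, 2, 3))
  list(gin = gin, grads = list(gamma = ggamma, beta = gbeta))
}

#' @export
layer_params.nn_batchnorm2d <- function(layer) {
  list(gamma = layer$gamma, beta = layer$beta)
}

#' @export
layer_set_params.nn_batchnorm2d <- function(layer, params) {
  layer$gamma <- as.numeric(params$gamma)
  layer$beta <- as.numeric(params$beta)
  layer
}

#' Batch-norm parameter bundle
#'
#' Per-channel scale, shift and running statistics in one list; the inputs
#' to conv/BN fusion.
#'
#' @param gamma,beta,mean,var Per-channel vectors.
#' @param eps Variance floor.
#' @return List of class `bn_params`.
#' @export
bn_params <- function(gamma, beta, mean, var, eps = 1e-5) {
  stopifnot(length(gamma) == length(beta), length(beta) == length(mean),
            length(mean) == length(var), all(var >= 0), eps > 0)
  structure(list(gamma = gamma, beta = beta, mean = mean, var = var, eps = eps),
            class = "bn_params")
}

bn_from_layer <- function(layer) {
  bn_params(layer$gamma, layer$beta, layer$stats$mean, layer$stats$var, layer$eps)
}

## ---- activation -------------------------------------------------------

#' Activation layer
#' @param kind One of `"relu6"`, `"hardswish"`, `"relu"`, `"identity"`.
#' @return An activation layer (parameter-free).
#' @export
nn_activation <- function(kind = "relu6") new_layer("activation", list(fun = kind))

#' @export
layer_forward.nn_activation <- function(layer, x, training = FALSE) {
  list(out = activation_forward(layer$fun, x), cache = list(x = x))
}

#' @export
layer_backward.nn_activation <- function(layer, cache, gout) {
  list(gin = gout * activation_grad(layer$fun, cache$x), grads = list())
}

## ---- linear -----------------------------------------------------------

#' Fully connected layer on (N, features) matrices
#' @param in_features,out_features Dimensions.
#' @param bias Include bias?
#' @param init `"kaiming"` or `"zero"`.
#' @return A linear layer.
#' @export
nn_linear <- function(in_features, out_features, bias = TRUE, init = "kaiming") {
  # uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)): FC layers here feed either a
  # softmax or an additive branch, not a BN, so a conservative scale keeps
  # initial logits small
  bound <- 1 / sqrt(in_features)
  w <- if (init == "zero") matrix(0, out_features, in_features)
       else matrix(runif(out_features * in_features, -bound, bound),
                   out_features, in_features)
  new_layer("linear", list(in_features = in_features, out_features = out_features,
                           weight = w, bias = if (bias) numeric(out_features) else NULL))
}

#' @export
layer_forward.nn_linear <- function(layer, x, training = FALSE) {
  y <- x %*% t(layer$weight)
  if (!is.null(layer$bias)) y <- sweep(y, 2, layer$bias, "+")
  list(out = y, cache = list(x = x))
}

#' @export
layer_backward.nn_linear <- function(layer, cache, gout) {
  grads <- list(weight = t(gout) %*% cache$x)
  if (!is.null(layer$bias)) grads$bias <- colSums(gout)
  list(gin = gout %*% layer$weight, grads = grads)
}

#' @export
layer_params.nn_linear <- function(layer) {
  p <- list(weight = layer$weight)
  if (!is.null(layer$bias)) p$bias <- layer$bias
  p
}

#' @export
layer_set_params.nn_linear <- function(layer, params) {
  layer$weight <- matrix(params$weight, nrow(layer$weight), ncol(layer$weight))
  if (!is.null(layer$bias)) layer$bias <- as.numeric(params$bias)
  layer
}

## ---- pooling ----------------------------------------------------------

#' Global average pooling layer: (N,C,H,W) -> (N,C)
#' @return A pooling layer.
#' @export
nn_global_pool <- function() new_layer("global_pool", list())

#' @export
layer_forward.nn_global_pool <- function(layer, x, training = FALSE) {
  list(out = global_pool_forward(x), cache = list(dims = fm_dims(x)))
}

#' @export
layer_backward.nn_global_pool <- function(layer, cache, gout) {
  list(gin = global_pool_backward(gout, cache$dims), grads = list())
}

#' 2x2 stride-2 average pooling layer
#' @return A pooling layer.
#' @export
nn_avgpool2x2 <- function() new_layer("avgpool2x2", list())

#' @export
layer_forward.nn_avgpool2x2 <- function(layer, x, training = FALSE) {
  list(out = avgpool2x2_forward(x), cache = list(dims = fm_dims(x)))
}

#' @export
layer_backward.nn_avgpool2x2 <- function(layer, cache, gout) {
  list(gin = avgpool2x2_backward(gout, cache$dims), grads = list())
}

## ---- sequential & defaults -------------------------------------------

#' Sequential container
#' @param layers Named list of layers, applied in order.
#' @return A sequential layer.
#' @export
nn_sequential <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    names(layers) <- sprintf("l%02d", seq_along(layers))
  new_layer("sequential", list(layers = layers))
}

#' @export
layer_forward.nn_sequential <- function(layer, x, training = FALSE) {
  caches <- vector("list", length(layer$layers))
  names(caches) <- names(layer$layers)
  for (i in seq_along(layer$layers)) {
    r <- layer_forward(layer$layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

#' @export
layer_backward.nn_sequential <- function(layer, cache, gout) {
  grads <- vector("list", length(layer$layers))
  names(grads) <- names(layer$layers)
  for (i in rev(seq_along(layer$layers))) {
    r <- layer_backward(layer$layers[[i]], cache[[i]], gout)
    gout <- r$gin
    grads[[i]] <- r$grads
  }
  list(gin = gout, grads = grads)
}

# Default recursion for composites holding children in $layers.
#' @export
layer_params.nn_layer <- function(layer) {
  if (is.null(layer$layers)) return(list())
  lapply(layer$layers, layer_params)
}

#' @export
layer_set_params.nn_layer <- function(layer, params) {
  if (is.null(layer$layers)) return(layer)
  for (nm in names(layer$layers))
    if (!is.null(params[[nm]]))
      layer$layers[[nm]] <- layer_set_params(layer$layers[[nm]], params[[nm]])
  layer
}

## ---- parameter flattening --------------------------------------------

#' Flatten a nested parameter list to dotted keys
#'
#' The dotted-key layout (`stage.block.layer.param`) is the serialized
#' weight-archive contract used by [save_weights()].
#'
#' @param params Nested named list of arrays.
#' @param prefix Key prefix (used in recursion).
#' @return Flat named list of numeric arrays.
#' @export
flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    p <- params[[nm]]
    if (is.list(p)) out <- c(out, flatten_params(p, key))
    else out[[key]] <- p
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- insert_nested(out, parts, flat[[key]])
  }
  out
}

insert_nested <- function(lst, parts, value) {
  if (length(parts) == 1) {
    lst[[parts]] <- value
    return(lst)
  }
  head_part <- parts[1]
  if (is.null(lst[[head_part]])) lst[[head_part]] <- list()
  lst[[head_part]] <- insert_nested(lst[[head_part]], parts[-1], value)
  lst
}

n_params <- function(layer) {
  sum(vapply(flatten_params(layer_params(layer)), length, numeric(1)))
}
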