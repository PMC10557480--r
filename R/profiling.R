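# Parameter / FLOP / MAdd accounting under one pinned convention:
#   * a conv or FC multiply-accumulate counts as 1 FLOP; MAdd counts
#     multiplies and adds separately (2*MAC - 1 per output element), plus
#     1 add per output element where a bias is present;
#   * inference batch norm costs 2 ops per element (scale + shift);
#   * activations, pooling and residual adds cost 1 op per element;
#   * sigmoid costs 4 ops per element.
# All comparisons in the package use this one convention so ratios between
# models are internally consistent.

prof_row <- function(name, type, params, flops, madd, out_shape) {
  data.frame(name = name, type = type, params = params, flops = flops,
             madd = madd, out_shape = paste(out_shape, collapse = "x"),
             stringsAsFactors = FALSE)
}

#' Per-layer profile
#' @param layer A layer object.
#' @param in_shape Input shape `c(C, H, W)` (or feature count for layers on
#'   matrices).
#' @param name Row label.
#' @return List with `rows` (data frame) and `out_shape`.
#' @export
layer_profile <- function(layer, in_shape, name = layer$kind) UseMethod("layer_profile")

#' @export
layer_profile.nn_conv2d <- function(layer, in_shape, name = layer$kind) {
  K <- layer$kernel_size
  ho <- (in_shape[2] + 2 * layer$padding - K) %/% layer$stride + 1
  wo <- (in_shape[3] + 2 * layer$padding - K) %/% layer$stride + 1
  out_el <- layer$out_channels * ho * wo
  macs_per_out <- K^2 * layer$in_channels / layer$groups
  flops <- out_el * macs_per_out
  madd <- out_el * (2 * macs_per_out - 1)
  if (!is.null(layer$bias)) { flops <- flops + out_el; madd <- madd + out_el }
  list(rows = prof_row(name, "conv2d", n_params(layer), flops, madd,
                       c(layer$out_channels, ho, wo)),
       out_shape = c(layer$out_channels, ho, wo))
}

#' @export
layer_profile.nn_batchnorm2d <- function(layer, in_shape, name = layer$kind) {
  el <- prod(in_shape)
  list(rows = prof_row(name, "batchnorm", n_params(layer), 2 * el, 2 * el,
                       in_shape),
       out_shape = in_shape)
}

#' @export
layer_profile.nn_activation <- function(layer, in_shape, name = layer$kind) {
  el <- prod(in_shape)
  list(rows = prof_row(name, layer$fun, 0, el, el, in_shape),
       out_shape = in_shape)
}

#' @export
layer_profile.nn_linear <- function(layer, in_shape, name = layer$kind) {
  macs <- layer$in_features * layer$out_features
  flops <- macs
  madd <- (2 * layer$in_features - 1) * layer$out_features
  if (!is.null(layer$bias)) {
    flops <- flops + layer$out_features
    madd <- madd + layer$out_features
  }
  list(rows = prof_row(name, "linear", n_params(layer), flops, madd,
                       layer$out_features),
       out_shape = layer$out_features)
}

#' @export
layer_profile.nn_global_pool <- function(layer, in_shape, name = layer$kind) {
  el <- prod(in_shape)
  list(rows = prof_row(name, "global_pool", 0, el, el, in_shape[1]),
       out_shape = in_shape[1])
}

#' @export
layer_profile.nn_avgpool2x2 <- function(layer, in_shape, name = layer$kind) {
  el <- prod(in_shape)
  out <- c(in_shape[1], in_shape[2] / 2, in_shape[3] / 2)
  list(rows = prof_row(name, "avgpool", 0, el, el, out), out_shape = out)
}

#' @export
layer_profile.nn_eca <- function(layer, in_shape, name = layer$kind) {
  el <- prod(in_shape)
  C <- in_shape[1]
  k <- layer$k
  flops <- el + C * k + 4 * C + el          # pool, conv1d, sigmoid, scale
  madd <- el + C * (2 * k - 1) + 4 * C + el
  list(rows = prof_row(name, "eca", k, flops, madd, in_shape),
       out_shape = in_shape)
}

#' @export
layer_profile.nn_grouped_fc <- function(layer, in_shape, name = layer$kind) {
  # in_shape here is the partition shape (C, h, w); cost is per partition
  hw <- layer$h * layer$w
  in_pg <- hw * layer$in_channels / layer$groups
  out_el <- hw * layer$out_channels
  macs <- out_el * in_pg
  flops <- macs
  madd <- out_el * (2 * in_pg - 1)
  if (!is.null(layer$bias)) { flops <- flops + out_el; madd <- madd + out_el }
  out <- c(layer$out_channels, layer$h, layer$w)
  list(rows = prof_row(name, "grouped_fc", n_params(layer), flops, madd, out),
       out_shape = out)
}

#' @export
layer_profile.nn_repmlp <- function(layer, in_shape, name = layer$kind) {
  C <- layer$channels; o <- layer$out_channels
  h <- layer$h; w <- layer$w
  P <- (in_shape[2] / h) * (in_shape[3] / w)   # partitions per image
  part_el <- C * h * w
  rows <- list()
  fl <- 0; md <- 0; par <- 0
  add_cost <- function(f, m) { fl <<- fl + P * f; md <<- md + P * m }
  # global perceptron: pool, fc1, relu, fc2, add
  add_cost(part_el, part_el)
  f1 <- layer_profile(layer$layers$fc1, C)
  f2 <- layer_profile(layer$layers$fc2, C / layer$rho)
  add_cost(f1$rows$flops + f2$rows$flops + C / layer$rho + part_el,
           f1$rows$madd + f2$rows$madd + C / layer$rho + part_el)
  par <- par + f1$rows$params + f2$rows$params
  # partition perceptron
  pf <- layer_profile(layer$layers$part_fc, c(C, h, w))
  add_cost(pf$rows$flops, pf$rows$madd)
  par <- par + pf$rows$params
  if (!layer$deployed) {
    par <- par + n_params(layer$layers$part_bn)
    add_cost(2 * o * h * w, 2 * o * h * w)
    for (K in layer$kernels) {
      cv <- layer$layers[[sprintf("local%d_conv", K)]]
      cp <- layer_profile(cv, c(C, h, w))
      add_cost(cp$rows$flops + 2 * o * h * w + o * h * w,  # conv, BN, add
               cp$rows$madd + 2 * o * h * w + o * h * w)
      par <- par + cp$rows$params + n_params(layer$layers[[sprintf("local%d_bn", K)]])
    }
  }
  out <- c(o, in_shape[2], in_shape[3])
  list(rows = prof_row(name, "repmlp", par, fl, md, out), out_shape = out)
}

profile_children <- function(layers, in_shape, prefix, use_residual = FALSE) {
  rows <- list()
  shape <- in_shape
  for (nm in names(layers)) {
    p <- layer_profile(layers[[nm]], shape, name = paste(prefix, nm, sep = "."))
    rows[[nm]] <- p$rows
    shape <- p$out_shape
  }
  if (use_residual) {
    el <- prod(shape)
    rows$residual <- prof_row(paste(prefix, "residual_add", sep = "."),
                              "add", 0, el, el, shape)
  }
  list(rows = do.call(rbind, rows), out_shape = shape)
}

#' @export
layer_profile.nn_sequential <- function(layer, in_shape, name = layer$kind) {
  profile_children(layer$layers, in_shape, name)
}

#' @export
layer_profile.nn_inverted_residual <- function(layer, in_shape, name = layer$kind) {
  profile_children(layer$layers, in_shape, name, layer$use_residual)
}

#' @export
layer_profile.nn_bottleneck_repmlp <- function(layer, in_shape, name = layer$kind) {
  profile_children(layer$layers, in_shape, name, layer$use_residual)
}

#' @export
layer_profile.repmlp_model <- function(layer, in_shape, name = "model") {
  profile_children(layer$layers, in_shape, name)
}

## ---- user-facing counters --------------------------------------------

#' Count trainable parameters
#'
#' Counts all trainable weights and biases, including batch-norm affine
#' parameters (running statistics are buffers and excluded).
#'
#' @param network A built model, any layer, or a reference parameter
#'   network.
#' @return Integer-valued parameter count.
#' @export
count_params <- function(network) UseMethod("count_params")

#' @export
count_params.nn_layer <- function(network) n_params(network)

#' @export
count_params.param_network <- function(network) sum(network$layers$params)

#' Parameter count in millions at printed precision
#' @param network As in [count_params()].
#' @param digits Decimal places (tables print 2).
#' @return `round(count_params(network) / 1e6, digits)`.
#' @export
params_m <- function(network, digits = 2) round(count_params(network) / 1e6, digits)

#' Count FLOPs and MAdd for one input image
#'
#' Shape-propagating walk over the network under the pinned counting
#' convention (see the package profiler docs): conv/FC multiply-accumulates
#' count 1 FLOP; BN 2 ops per element; activations, pooling and residual
#' adds 1 op per element; sigmoid 4 ops per element.  MAdd counts
#' multiplies and adds separately.
#'
#' @param network A built model (or any layer).
#' @param input_shape `c(C, H, W)`; default `c(3, 224, 224)`.
#' @return List with `flops` and `madd` (raw op counts).
#' @export
count_flops <- function(network, input_shape = c(3, 224, 224)) {
  p <- layer_profile(network, input_shape)
  list(flops = sum(p$rows$flops), madd = sum(p$rows$madd))
}

#' Full per-layer profile report
#'
#' @param network A built model (or any layer).
#' @param input_shape `c(C, H, W)`.
#' @return A tibble of per-layer rows plus a `totals` attribute
#'   (params, flops, madd; raw counts).
#' @export
profile_model <- function(network, input_shape = c(3, 224, 224)) {
  p <- layer_profile(network, input_shape)
  rows <- tibble::as_tibble(p$rows)
  attr(rows, "totals") <- list(params = sum(rows$params),
                               flops = sum(rows$flops),
                               madd = sum(rows$madd))
  rows
}

#' Percent reduction of a candidate relative to a reference
#'
#' `100 * (reference - candidate) / reference`; e.g. parameter reduction of
#' the improved model over its baseline.
#'
#' @param reference Baseline value (> 0).
#' @param candidate Comparison value.
#' @return Percentage.
#' @export
percent_reduction <- function(reference, candidate) {
  if (reference <= 0) stop("reference must be positive")
  100 * (reference - candidate) / reference
}
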