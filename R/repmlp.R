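# RepMLP: an MLP-style block of fully connected layers organized as global,
# partition, and local perceptrons.  The training form carries per-group
# convolution branches (the local perceptron) that are folded exactly into
# the partition FC for deployment (see reparam.R).

#' Split a feature map into non-overlapping partitions
#'
#' Tiles each `H x W` map into `(H/h) x (W/w)` patches of size `h x w` and
#' stacks them along the batch axis.  Partition order is row-major over the
#' patch grid (the column index varies fastest, then the row, then the
#' original batch index); this ordering is part of the serialized-weight
#' contract.
#'
#' @param x Feature map `(N, C, H, W)`; `H` must be divisible by `h` and
#'   `W` by `w`.
#' @param h,w Partition height and width.
#' @return Array `(N * (H/h) * (W/w), C, h, w)`.
#' @export
partition_split <- function(x, h, w) {
  d <- fm_dims(x)
  if (d[3] %% h != 0 || d[4] %% w != 0)
    stop("H and W must be divisible by the partition size")
  nh <- d[3] / h; nw <- d[4] / w
  x6 <- array(x, c(d[1], d[2], h, nh, w, nw))
  y <- aperm(x6, c(6, 4, 1, 2, 3, 5))   # (nw, nh, N, C, h, w)
  dim(y) <- c(nw * nh * d[1], d[2], h, w)
  y
}

#' Merge partitions back into a feature map
#'
#' Exact inverse of [partition_split()]; `partition_merge(partition_split(x,
#' h, w), ...)` reproduces `x` bit-for-bit.
#'
#' @param p Partitioned array `(N * (H/h) * (W/w), C, h, w)`.
#' @param n Original batch size.
#' @param H,W Original map height and width.
#' @return Feature map `(n, C, H, W)`.
#' @export
partition_merge <- function(p, n, H, W) {
  d <- fm_dims(p)
  h <- d[3]; w <- d[4]
  nh <- H / h; nw <- W / w
  if (d[1] != n * nh * nw) stop("partition count does not match n, H, W")
  y6 <- array(p, c(nw, nh, n, d[2], h, w))
  x6 <- aperm(y6, c(3, 4, 5, 2, 6, 1))  # (N, C, h, nh, w, nw)
  dim(x6) <- c(n, d[2], H, W)
  x6
}

## ---- grouped FC -------------------------------------------------------

#' Grouped fully connected layer over partitions
#'
#' Flattens each `h x w x (C/g)` group of a partition to a vector, applies
#' one dense matrix per group, and reshapes back to `(o/g) x h x w`.  The
#' within-group flattening order is channel-fastest, then rows, then
#' columns (R column-major over `(C/g, h, w)`).
#'
#' @param in_channels,out_channels Channel counts, both divisible by
#'   `groups`.
#' @param h,w Partition size the layer operates on.
#' @param groups Number of groups.
#' @param bias Per-output-channel bias (used by the deployed form; the
#'   training form relies on batch norm instead).
#' @param init `"kaiming"` or `"zero"`.
#' @return A grouped FC layer.
#' @export
nn_grouped_fc <- function(in_channels, out_channels, h, w, groups = 1L,
                          bias = FALSE, init = "kaiming") {
  stopifnot(in_channels %% groups == 0, out_channels %% groups == 0)
  in_pg <- h * w * in_channels / groups
  out_pg <- h * w * out_channels / groups
  wt <- if (init == "zero") array(0, c(out_pg, in_pg, groups))
        else array(kaiming_uniform(c(out_pg, in_pg, groups), in_pg),
                   c(out_pg, in_pg, groups))
  new_layer("grouped_fc", list(
    in_channels = in_channels, out_channels = out_channels,
    h = h, w = w, groups = as.integer(groups),
    weight = wt, bias = if (bias) numeric(out_channels) else NULL))
}

#' @export
layer_forward.nn_grouped_fc <- function(layer, x, training = FALSE) {
  d <- fm_dims(x)
  g <- layer$groups
  cg_in <- layer$in_channels / g
  cg_out <- layer$out_channels / g
  h <- layer$h; w <- layer$w
  if (d[2] != layer$in_channels || d[3] != h || d[4] != w)
    stop("grouped_fc: partition shape mismatch")
  out <- array(0, c(d[1], layer$out_channels, h, w))
  for (gi in seq_len(g)) {
    ci <- ((gi - 1) * cg_in + 1):(gi * cg_in)
    co <- ((gi - 1) * cg_out + 1):(gi * cg_out)
    xm <- x[, ci, , , drop = FALSE]
    dim(xm) <- c(d[1], cg_in * h * w)
    ym <- xm %*% t(matrix(layer$weight[, , gi],
                          nrow = cg_out * h * w, ncol = cg_in * h * w))
    out[, co, , ] <- array(ym, c(d[1], cg_out, h, w))
  }
  if (!is.null(layer$bias))
    out <- out + array(rep(layer$bias, each = d[1]), dim(out))
  list(out = out, cache = list(x = x))
}

#' @export
layer_backward.nn_grouped_fc <- function(layer, cache, gout) {
  x <- cache$x
  d <- fm_dims(x)
  g <- layer$groups
  cg_in <- layer$in_channels / g
  cg_out <- layer$out_channels / g
  h <- layer$h; w <- layer$w
  gin <- array(0, d)
  gw <- array(0, dim(layer$weight))
  for (gi in seq_len(g)) {
    ci <- ((gi - 1) * cg_in + 1):(gi * cg_in)
    co <- ((gi - 1) * cg_out + 1):(gi * cg_out)
    xm <- x[, ci, , , drop = FALSE]
    dim(xm) <- c(d[1], cg_in * h * w)
    gym <- gout[, co, , , drop = FALSE]
    dim(gym) <- c(d[1], cg_out * h * w)
    Wg <- matrix(layer$weight[, , gi], cg_out * h * w, cg_in * h * w)
    gw[, , gi] <- t(gym) %*% xm
    gin[, ci, , ] <- array(gym %*% Wg, c(d[1], cg_in, h, w))
  }
  grads <- list(weight = gw)
  if (!is.null(layer$bias))
    grads$bias <- colSums(matrix(rowSums(matrix(gout, nrow = d[1] * d[2])),
                                 d[1], d[2]))
  list(gin = gin, grads = grads)
}

#' @export
layer_params.nn_grouped_fc <- function(layer) {
  p <- list(weight = layer$weight)
  if (!is.null(layer$bias)) p$bias <- layer$bias
  p
}

#' @export
layer_set_params.nn_grouped_fc <- function(layer, params) {
  layer$weight <- array(params$weight, dim(layer$weight))
  if (!is.null(layer$bias)) layer$bias <- as.numeric(params$bias)
  layer
}

## ---- RepMLP block -----------------------------------------------------

#' RepMLP block
#'
#' Three perceptrons over partitioned feature maps:
#' * global: each partition is average-pooled to a channel vector, passed
#'   through a two-layer FC bottleneck (reduction `rho`, ReLU in between)
#'   and added back to the partition (a squeeze-excite-like additive path
#'   that relates partitions to their content);
#' * partition: a grouped FC mixing all positions (and channels within a
#'   group) of each partition, followed by batch norm;
#' * local (training form only): parallel depthwise-style convolution
#'   branches of odd kernel sizes, each with its own batch norm, summed
#'   into the partition output to re-inject local structure.
#'
#' [reparameterize()] folds the local branches and the partition BN into
#' the grouped FC for deployment.
#'
#' @param channels Input channel count `C`.
#' @param h,w Partition size (must divide the map's `H`, `W` at forward
#'   time).
#' @param groups Grouping of the partition FC and local convolutions;
#'   defaults to `channels` (per-channel mixing, the configuration selected
#'   by the shipped calibration).
#' @param rho Global-perceptron channel reduction (default 4).
#' @param kernels Odd local-perceptron kernel sizes, a subset of
#'   `c(1, 3, 5)` no larger than `min(h, w)`.
#' @param out_channels Output channels `o` (divisible by `groups`);
#'   defaults to `channels`.
#' @return A RepMLP layer (training form).
#' @export
nn_repmlp <- function(channels, h, w, groups = channels, rho = 4,
                      kernels = NULL, out_channels = channels) {
  if (is.null(kernels)) kernels <- c(1, 3, 5)[c(1, 3, 5) <= min(h, w)]
  stopifnot(channels %% groups == 0, out_channels %% groups == 0,
            all(kernels %in% c(1, 3, 5)), all(kernels <= min(h, w)),
            length(kernels) >= 1)
  if (channels %% rho != 0)
    stop("channels must be divisible by the global reduction rho")
  layers <- list(
    fc1 = nn_linear(channels, channels / rho, bias = TRUE),
    fc2 = nn_linear(channels / rho, channels, bias = TRUE),
    part_fc = nn_grouped_fc(channels, out_channels, h, w, groups),
    part_bn = nn_batchnorm2d(out_channels))
  for (K in kernels) {
    layers[[sprintf("local%d_conv", K)]] <-
      nn_conv2d(channels, out_channels, K, padding = (K - 1) / 2,
                groups = groups)
    layers[[sprintf("local%d_bn", K)]] <- nn_batchnorm2d(out_channels)
  }
  new_layer("repmlp", list(
    channels = channels, out_channels = out_channels,
    h = as.integer(h), w = as.integer(w), groups = as.integer(groups),
    rho = rho, kernels = as.integer(kernels), deployed = FALSE,
    layers = layers))
}

broadcast_nc <- function(m, d) array(rep(as.numeric(m), times = d[3] * d[4]), d)

#' @export
layer_forward.nn_repmlp <- function(layer, x, training = FALSE) {
  d <- fm_dims(x)
  pt <- partition_split(x, layer$h, layer$w)
  pd <- dim(pt)
  # global perceptron
  v <- global_pool_forward(pt)
  r1 <- layer_forward(layer$layers$fc1, v, training)
  a <- relu(r1$out)
  r2 <- layer_forward(layer$layers$fc2, a, training)
  ptg <- pt + broadcast_nc(r2$out, pd)
  # partition perceptron
  rp <- layer_forward(layer$layers$part_fc, ptg, training)
  if (layer$deployed) {
    out_pt <- rp$out
    rb <- NULL
    local_caches <- NULL
  } else {
    rb <- layer_forward(layer$layers$part_bn, rp$out, training)
    out_pt <- rb$out
    # local perceptron
    local_caches <- list()
    for (K in layer$kernels) {
      ck <- sprintf("local%d_conv", K); bk <- sprintf("local%d_bn", K)
      rc <- layer_forward(layer$layers[[ck]], ptg, training)
      rbn <- layer_forward(layer$layers[[bk]], rc$out, training)
      out_pt <- out_pt + rbn$out
      local_caches[[as.character(K)]] <- list(conv = rc$cache, bn = rbn$cache)
    }
  }
  out <- partition_merge(out_pt, d[1], d[3], d[4])
  list(out = out,
       cache = list(dims = d, pdims = pd, z1 = r1$cache, a_pre = r1$out,
                    fc2 = r2$cache, fc1 = r1$cache, part_fc = rp$cache,
                    part_bn = if (is.null(rb)) NULL else rb$cache,
                    local = local_caches, v_cache_dims = pd))
}

#' @export
layer_backward.nn_repmlp <- function(layer, cache, gout) {
  d <- cache$dims
  g_pt_out <- partition_split(gout, layer$h, layer$w)
  grads <- list()
  # partition branch
  if (layer$deployed) {
    g_fc_out <- g_pt_out
  } else {
    rb <- layer_backward(layer$layers$part_bn, cache$part_bn, g_pt_out)
    grads$part_bn <- rb$grads
    g_fc_out <- rb$gin
  }
  rp <- layer_backward(layer$layers$part_fc, cache$part_fc, g_fc_out)
  grads$part_fc <- rp$grads
  g_ptg <- rp$gin
  # local branches share g_pt_out
  if (!layer$deployed) {
    for (K in layer$kernels) {
      ck <- sprintf("local%d_conv", K); bk <- sprintf("local%d_bn", K)
      lc <- cache$local[[as.character(K)]]
      rbn <- layer_backward(layer$layers[[bk]], lc$bn, g_pt_out)
      grads[[bk]] <- rbn$grads
      rc <- layer_backward(layer$layers[[ck]], lc$conv, rbn$gin)
      grads[[ck]] <- rc$grads
      g_ptg <- g_ptg + rc$gin
    }
  }
  # global perceptron: ptg = pt + broadcast(fc2(relu(fc1(gap(pt)))))
  pd <- cache$pdims
  g_pt <- g_ptg
  g_z2 <- matrix(rowSums(matrix(g_ptg, nrow = pd[1] * pd[2])), pd[1], pd[2])
  r2 <- layer_backward(layer$layers$fc2, cache$fc2, g_z2)
  grads$fc2 <- r2$grads
  g_a <- r2$gin * (cache$a_pre > 0)
  r1 <- layer_backward(layer$layers$fc1, cache$fc1, g_a)
  grads$fc1 <- r1$grads
  g_pt <- g_pt + global_pool_backward(r1$gin, pd)
  gin <- partition_merge(g_pt, d[1], d[3], d[4])
  list(gin = gin, grads = grads)
}

#' RepMLP forward pass
#'
#' Functional form: split into partitions, add the global-perceptron
#' correction, apply the partition FC (+BN) and, in the training form, the
#' summed local convolution branches, then merge partitions back.
#'
#' @param x Feature map `(N, C, H, W)`.
#' @param block A RepMLP layer from [nn_repmlp()] (training or deployed
#'   form).
#' @param training Batch-norm mode.
#' @return Feature map `(N, out_channels, H, W)`.
#' @export
repmlp_forward <- function(x, block, training = FALSE) {
  layer_forward(block, x, training)$out
}

#' Global perceptron applied to partitions
#'
#' Average-pools each partition to a channel vector, runs it through the
#' FC bottleneck `C -> C/rho -> C` (ReLU in between) and adds the result
#' back to every position of the partition.
#'
#' @param partitions Array `(P, C, h, w)`.
#' @param fc1,fc2 Linear layers `C -> C/rho` and `C/rho -> C`.
#' @return Partitions, same shape.
#' @export
global_perceptron <- function(partitions, fc1, fc2) {
  v <- global_pool_forward(partitions)
  z <- layer_forward(fc2, relu(layer_forward(fc1, v)$out))$out
  partitions + broadcast_nc(z, dim(partitions))
}

#' Partition perceptron applied to partitions
#'
#' Grouped FC over the flattened partition followed by batch norm.
#'
#' @param partitions Array `(P, C, h, w)`.
#' @param fc A grouped FC layer.
#' @param bn A batch-norm layer over the output channels (or `NULL` for
#'   the deployed form, where the FC carries a fused bias).
#' @param training Batch-norm mode.
#' @return Partitions with `fc$out_channels` channels.
#' @export
partition_perceptron <- function(partitions, fc, bn = NULL, training = FALSE) {
  y <- layer_forward(fc, partitions, training)$out
  if (!is.null(bn)) y <- layer_forward(bn, y, training)$out
  y
}

#' Local perceptron applied to partitions
#'
#' Sum over parallel conv+BN branches; shapes are preserved by odd kernels
#' with same-padding.
#'
#' @param partitions Array `(P, C, h, w)`.
#' @param branches List of `list(conv = <conv layer>, bn = <bn layer>)`.
#' @param training Batch-norm mode.
#' @return The summed branch output (added to the partition-perceptron
#'   output by the caller).
#' @export
local_perceptron <- function(partitions, branches, training = FALSE) {
  out <- NULL
  for (b in branches) {
    y <- layer_forward(b$conv, partitions, training)$out
    if (!is.null(b$bn)) y <- layer_forward(b$bn, y, training)$out
    if (!identical(dim(y), dim(partitions)) &&
        !identical(dim(y)[c(1, 3, 4)], dim(partitions)[c(1, 3, 4)]))
      stop("local branch does not preserve partition shape")
    out <- if (is.null(out)) y else out + y
  }
  out
}
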