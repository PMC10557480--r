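# Structural re-parameterization: fold conv + batch-norm branches of a
# trained RepMLP into its partition FC so the deployed block is a pure MLP
# with identical outputs.

#' Fuse a batch-norm layer into the preceding convolution
#'
#' For inference-mode BN with statistics `(mu, var)` and affine `(gamma,
#' beta)`, returns weights `W'_c = gamma_c * W_c / sqrt(var_c + eps)` and
#' bias `b'_c = beta_c + gamma_c * (b_c - mu_c) / sqrt(var_c + eps)` so the
#' fused convolution reproduces conv+BN exactly.
#'
#' @param weight Conv weight array `(C_out, C_in/g, K, K)`.
#' @param bias Conv bias vector or `NULL`.
#' @param bn A [bn_params()] bundle with `C_out` channels.
#' @return List with fused `weight` and `bias`.
#' @export
fuse_bn_into_conv <- function(weight, bias, bn) {
  stopifnot(inherits(bn, "bn_params"))
  co <- dim(weight)[1]
  if (length(bn$gamma) != co) stop("BN channel count must match conv output")
  denom <- sqrt(bn$var + bn$eps)
  if (any(denom <= 0)) stop("non-positive BN variance")
  scale <- bn$gamma / denom
  w <- sweep(weight, 1, scale, "*")
  b0 <- if (is.null(bias)) numeric(co) else bias
  b <- bn$beta + scale * (b0 - bn$mean)
  list(weight = w, bias = b)
}

#' Convert a shape-preserving convolution into an equivalent FC matrix
#'
#' Builds the matrix `M` with `M %*% vec(partition) == vec(conv(partition))`
#' for every `C x h x w` partition, by probing: the convolution is applied
#' to each element of the identity basis (stacked as a batch) and the
#' outputs become the columns of `M`.  `vec()` is R column-major over
#' `(C, h, w)` (channel fastest).
#'
#' @param weight Conv weight `(o, C/g, K, K)` (same-padding assumed:
#'   `padding = (K-1)/2`).
#' @param h,w Partition size.
#' @param C Input channels.
#' @param groups Convolution groups.
#' @return Dense matrix of dimension `(h*w*o) x (h*w*C)`.
#' @export
conv_to_fc <- function(weight, h, w, C, groups = 1L) {
  K <- dim(weight)[3]
  o <- dim(weight)[1]
  n_in <- C * h * w
  basis <- array(0, c(n_in, C, h, w))
  idx <- cbind(seq_len(n_in),
               arrayInd(seq_len(n_in), c(C, h, w)))
  basis[idx] <- 1
  y <- conv2d_forward(basis, weight, NULL, stride = 1L,
                      padding = (K - 1) / 2, groups = groups)
  # column j of M is vec(conv(basis_j)); y is (n_in, o, h, w)
  M <- t(matrix(y, nrow = n_in))
  M
}

# Per-group fold of a fused conv into grouped-FC weight increments.
# Returns an array shaped like nn_grouped_fc weight (out_pg x in_pg x g).
conv_to_grouped_fc <- function(weight, h, w, C, o, groups) {
  K <- dim(weight)[3]
  cg_in <- C / groups
  cg_out <- o / groups
  out <- array(0, c(cg_out * h * w, cg_in * h * w, groups))
  n_in <- cg_in * h * w
  basis <- array(0, c(n_in, cg_in, h, w))
  idx <- cbind(seq_len(n_in), arrayInd(seq_len(n_in), c(cg_in, h, w)))
  basis[idx] <- 1
  for (gi in seq_len(groups)) {
    co <- ((gi - 1) * cg_out + 1):(gi * cg_out)
    wg <- weight[co, , , , drop = FALSE]
    y <- conv2d_forward(basis, wg, NULL, stride = 1L,
                        padding = (K - 1) / 2, groups = 1L)
    out[, , gi] <- t(matrix(y, nrow = n_in))
  }
  out
}

#' Re-parameterize a block or model for deployment
#'
#' @param object A RepMLP layer or a built model.
#' @param ... Unused.
#' @return The deployed-form object (identical outputs, conv branches
#'   folded away).
#' @export
reparameterize <- function(object, ...) UseMethod("reparameterize")

#' @describeIn reparameterize Fold the local conv+BN branches and the
#'   partition BN of a training-form RepMLP into its grouped FC (weight
#'   plus per-channel bias).  The global perceptron is left untouched.
#' @export
reparameterize.nn_repmlp <- function(object, ...) {
  if (object$deployed) stop("block is already in deployed form")
  fc <- object$layers$part_fc
  h <- object$h; w <- object$w
  C <- object$channels; o <- object$out_channels; g <- object$groups
  # fold partition BN into FC rows (per output channel, broadcast over
  # positions) and start the fused bias from it
  bn <- bn_from_layer(object$layers$part_bn)
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  bias <- bn$beta - scale * bn$mean
  wt <- fc$weight
  cg_out <- o / g
  for (gi in seq_len(g)) {
    co <- ((gi - 1) * cg_out + 1):(gi * cg_out)
    # rows of the group matrix are ordered channel-fastest
    row_scale <- rep(scale[co], times = h * w)
    wt[, , gi] <- wt[, , gi] * row_scale
  }
  # fold each local branch: fuse its BN, convert to grouped FC, accumulate
  for (K in object$kernels) {
    conv <- object$layers[[sprintf("local%d_conv", K)]]
    bnk <- bn_from_layer(object$layers[[sprintf("local%d_bn", K)]])
    fused <- fuse_bn_into_conv(conv$weight, conv$bias, bnk)
    wt <- wt + conv_to_grouped_fc(fused$weight, h, w, C, o, g)
    bias <- bias + fused$bias
  }
  dep <- object
  dep$deployed <- TRUE
  new_fc <- nn_grouped_fc(C, o, h, w, g, bias = TRUE, init = "zero")
  new_fc$weight <- wt
  new_fc$bias <- bias
  dep$layers <- list(fc1 = object$layers$fc1, fc2 = object$layers$fc2,
                     part_fc = new_fc)
  dep
}
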