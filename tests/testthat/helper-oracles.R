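# Independent oracles used across the suite.  All are direct-summation /
# brute-force implementations kept deliberately separate from the package's
# im2col + gemm path.

# Direct sliding-window convolution by explicit summation.
naive_conv2d <- function(x, w, bias = NULL, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); wd <- dim(w); K <- wd[3]
  ho <- (d[3] + 2 * pad - K) %/% stride + 1
  wo <- (d[4] + 2 * pad - K) %/% stride + 1
  cing <- wd[2]; coutg <- wd[1] / groups
  y <- array(0, c(d[1], wd[1], ho, wo))
  for (n in seq_len(d[1])) for (oc in seq_len(wd[1])) {
    g <- (oc - 1) %/% coutg
    for (oh in seq_len(ho)) for (ow in seq_len(wo)) {
      s <- if (is.null(bias)) 0 else bias[oc]
      for (i in seq_len(cing)) for (kh in seq_len(K)) for (kw in seq_len(K)) {
        hi <- (oh - 1) * stride - pad + kh
        wi <- (ow - 1) * stride - pad + kw
        if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
          s <- s + x[n, g * cing + i, hi, wi] * w[oc, i, kh, kw]
      }
      y[n, oc, oh, ow] <- s
    }
  }
  y
}

# Inference-mode batch norm by hand.
naive_bn <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[2]))
    y[, c, , ] <- gamma[c] * (x[, c, , ] - mean[c]) / sqrt(var[c] + eps) + beta[c]
  y
}

# ECA by explicit GAP -> zero-pad -> slide -> sigmoid -> scale.
naive_eca <- function(x, w) {
  d <- dim(x)
  k <- length(w); half <- (k - 1) / 2
  y <- x
  for (n in seq_len(d[1])) {
    v <- apply(x[n, , , , drop = FALSE], 2, mean)
    vp <- c(rep(0, half), v, rep(0, half))
    s <- sapply(seq_len(d[2]), function(c) sum(w * vp[c:(c + k - 1)]))
    gate <- 1 / (1 + exp(-s))
    for (c in seq_len(d[2])) y[n, c, , ] <- x[n, c, , ] * gate[c]
  }
  y
}

# Identity-BN layer (gamma 1, beta 0, mean 0, var 1): passthrough at
# inference (eps kept tiny so the identity is numerically exact).
identity_bn <- function(channels) nn_batchnorm2d(channels, eps = 1e-12)

# Give every BN in a layer tree random non-trivial statistics/affine so
# fusion tests exercise the general case.
randomize_bn_tree <- function(l) {
  if (inherits(l, "nn_batchnorm2d")) {
    l$gamma <- runif(l$channels, 0.5, 1.5)
    l$beta <- rnorm(l$channels, 0, 0.2)
    l$stats$mean <- rnorm(l$channels, 0, 0.3)
    l$stats$var <- runif(l$channels, 0.5, 2)
  } else if (!is.null(l$layers)) {
    l$layers <- lapply(l$layers, randomize_bn_tree)
  }
  l
}

# Set every trainable parameter of a layer tree to zero.
zero_params_tree <- function(layer) {
  flat <- flatten_params(layer_params(layer))
  flat <- lapply(flat, function(p) array(0, dim(p) %||% length(p)))
  layer_set_params(layer, repmlpnet:::unflatten_params(flat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_fm <- function(n, c, h, w) array(rnorm(n * c * h * w), c(n, c, h, w))

# Small class set spanning crops and conditions, ids remapped to 0..k-1.
smoke_class_set <- function(k = 4) {
  all25 <- leaf_class_models(25)
  cls <- all25[(seq_len(k) - 1) * 6 %% 25 + 1]
  for (i in seq_along(cls)) cls[[i]]$class_id <- i - 1L
  cls
}
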