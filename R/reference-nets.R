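# Parameter-count reference builds for the comparison networks.  Only their
# trainable-parameter totals are needed (the comparison tables), so they are
# described as per-layer parameter ledgers rather than runnable networks.
# Conventions: convolutions are bias-free and followed by batch norm with
# affine scale/shift (2 trainable values per channel); the classifier is a
# biased linear layer.

param_network <- function(name, rows) {
  structure(list(name = name,
                 layers = data.frame(name = vapply(rows, `[[`, "", "name"),
                                     type = vapply(rows, `[[`, "", "type"),
                                     params = vapply(rows, `[[`, 0, "params"),
                                     stringsAsFactors = FALSE)),
            class = "param_network")
}

conv_bn_p <- function(name, cin, cout, k, groups = 1) {
  list(name = name, type = "conv_bn", params = k * k * cin * cout / groups + 2 * cout)
}

linear_p <- function(name, cin, cout) {
  list(name = name, type = "linear", params = cin * cout + cout)
}

#' ResNet18 parameter ledger
#'
#' Standard 18-layer residual network: 7 x 7 stem, four stages of two basic
#' blocks (3 x 3 + 3 x 3, with a 1 x 1 projection shortcut at each stage
#' transition), global pooling and a linear classifier.
#'
#' @param num_classes Classifier width.
#' @return A `param_network` usable with [count_params()].
#' @export
resnet18_reference <- function(num_classes = 25) {
  rows <- list(conv_bn_p("stem", 3, 64, 7))
  widths <- c(64, 128, 256, 512)
  cin <- 64
  for (si in seq_along(widths)) {
    w <- widths[si]
    for (bi in 1:2) {
      bin <- if (bi == 1) cin else w
      rows <- c(rows, list(
        conv_bn_p(sprintf("layer%d.%d.conv1", si, bi), bin, w, 3),
        conv_bn_p(sprintf("layer%d.%d.conv2", si, bi), w, w, 3)))
      if (bi == 1 && bin != w)
        rows <- c(rows, list(conv_bn_p(sprintf("layer%d.%d.down", si, bi), bin, w, 1)))
    }
    cin <- w
  }
  rows <- c(rows, list(linear_p("fc", 512, num_classes)))
  param_network("ResNet18", rows)
}

#' ShuffleNetV2 (width 1.0) parameter ledger
#'
#' 24-channel stem, three stages of channel-split units (stage widths 116,
#' 232, 464 with 4, 8, 4 units; the first unit of each stage is the
#' stride-2 two-branch variant), a 1 x 1 conv to 1,024 channels, global
#' pooling and a linear classifier.
#'
#' @param num_classes Classifier width.
#' @return A `param_network` usable with [count_params()].
#' @export
shufflenet_v2_reference <- function(num_classes = 25) {
  unit_down <- function(name, cin, cout) {
    br <- cout / 2
    list(
      conv_bn_p(paste0(name, ".b1.dw"), cin, cin, 3, groups = cin),
      conv_bn_p(paste0(name, ".b1.pw"), cin, br, 1),
      conv_bn_p(paste0(name, ".b2.pw1"), cin, br, 1),
      conv_bn_p(paste0(name, ".b2.dw"), br, br, 3, groups = br),
      conv_bn_p(paste0(name, ".b2.pw2"), br, br, 1))
  }
  unit_basic <- function(name, c) {
    br <- c / 2
    list(
      conv_bn_p(paste0(name, ".pw1"), br, br, 1),
      conv_bn_p(paste0(name, ".dw"), br, br, 3, groups = br),
      conv_bn_p(paste0(name, ".pw2"), br, br, 1))
  }
  rows <- list(conv_bn_p("stem", 3, 24, 3))
  cfg <- list(list(c = 116, n = 4), list(c = 232, n = 8), list(c = 464, n = 4))
  cin <- 24
  for (si in seq_along(cfg)) {
    st <- cfg[[si]]
    rows <- c(rows, unit_down(sprintf("stage%d.0", si + 1), cin, st$c))
    for (ui in seq_len(st$n - 1))
      rows <- c(rows, unit_basic(sprintf("stage%d.%d", si + 1, ui), st$c))
    cin <- st$c
  }
  rows <- c(rows, list(conv_bn_p("conv5", 464, 1024, 1),
                       linear_p("fc", 1024, num_classes)))
  param_network("ShuffleNetV2x1.0", rows)
}
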