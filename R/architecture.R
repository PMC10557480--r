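# Model assembly: the seven-stage MobileNetV2 backbone with optional
# replacement of late stages by the improved bottleneck in which a RepMLP
# performs feature extraction at reduced channel width.

# Backbone stage table: expansion t, output channels c, repeats n, stride s
# of the first block of each stage.
backbone_stages <- function() {
  list(
    B1 = list(t = 1, c = 16,  n = 1, s = 1),
    B2 = list(t = 6, c = 24,  n = 2, s = 2),
    B3 = list(t = 6, c = 32,  n = 3, s = 2),
    B4 = list(t = 6, c = 64,  n = 4, s = 2),
    B5 = list(t = 6, c = 96,  n = 3, s = 1),
    B6 = list(t = 6, c = 160, n = 3, s = 2),
    B7 = list(t = 6, c = 320, n = 1, s = 1))
}

#' RepMLP internals calibration
#'
#' The internals the block sketch leaves open (partition size, FC grouping,
#' global reduction, local kernel set) are fixed here, once, by the
#' calibration documented in the methods vignette (reproduced by
#' `scripts/calibrate.R`): partition FCs are per-channel (`groups =
#' channels`), the global reduction is `rho = 4`, maps whose resolution is
#' a multiple of 7 (and larger than 7) are tiled into 7 x 7 partitions,
#' and smaller maps use per-position mixing (`h = w = 1`).  Local kernels
#' are `{1, 3, 5}` clipped to the partition size.
#'
#' @param channels Channel width the RepMLP runs at.
#' @param resolution Feature-map side length at that stage.
#' @return List with `h`, `w`, `groups`, `rho`, `kernels`.
#' @export
repmlp_calibration <- function(channels, resolution) {
  h <- if (resolution > 7 && resolution %% 7 == 0) 7L else 1L
  list(h = h, w = h, groups = channels, rho = 4,
       kernels = c(1L, 3L, 5L)[c(1, 3, 5) <= h])
}

#' Model specification
#'
#' Describes one member of the model family: which backbone stages use the
#' RepMLP bottleneck, the channel-reduction factor `r`, the head size, and
#' the two accuracy switches (ECA after every block, Hardswish inside the
#' RepMLP bottlenecks).  The default is the deployment configuration:
#' RepMLP in stages B5-B7, \code{r = 4}, ECA and Hardswish on, 25 classes,
#' 224 x 224 input.
#'
#' @param repmlp_stages Character subset of `c("B4","B5","B6","B7")`.
#' @param r Channel-reduction factor, one of 2, 4, 8.
#' @param num_classes Classifier width.
#' @param use_eca Insert an ECA module after every block instance?
#' @param use_hardswish Use Hardswish (instead of ReLU6) in the RepMLP
#'   bottlenecks?
#' @param input_size Square input resolution the model is built for (the
#'   partition sizes of the RepMLP stages follow from it).
#' @param seed Weight-initialization seed used by [build_model()].
#' @return A `model_spec` object.
#' @export
model_spec <- function(repmlp_stages = c("B5", "B6", "B7"), r = 4,
                       num_classes = 25, use_eca = TRUE,
                       use_hardswish = TRUE, input_size = 224, seed = 1L) {
  if (!r %in% c(2, 4, 8)) stop("r must be one of 2, 4, 8")
  if (!all(repmlp_stages %in% c("B4", "B5", "B6", "B7")))
    stop("repmlp stages must be a subset of B4..B7")
  structure(list(repmlp_stages = repmlp_stages, r = r,
                 num_classes = num_classes, use_eca = use_eca,
                 use_hardswish = use_hardswish,
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "model_spec")
}

#' Build a model-family variant specification
#'
#' Members of the stage-selection and channel-reduction ablation grids.
#' Those grids were run on 10-class 32 x 32 imagery, so the default input
#' size here is 32; an empty `stages` set gives the plain MobileNetV2
#' baseline.
#'
#' @param stages Character subset of `c("B4","B5","B6","B7")` (possibly
#'   empty).
#' @param r Channel-reduction factor, one of 2, 4, 8.
#' @param num_classes Classifier width.
#' @param use_eca,use_hardswish Accuracy switches (off by default, as in
#'   the ablation grids).
#' @param input_size Input resolution.
#' @param seed Initialization seed.
#' @return A `model_spec`.
#' @export
make_variant <- function(stages, r = 4, num_classes = 10, use_eca = FALSE,
                         use_hardswish = FALSE, input_size = 32, seed = 1L) {
  model_spec(stages, r, num_classes, use_eca, use_hardswish, input_size, seed)
}

#' Plain MobileNetV2 specification
#'
#' @param num_classes Classifier width.
#' @param input_size Input resolution.
#' @param seed Initialization seed.
#' @return A `model_spec` with no RepMLP stages, no ECA, ReLU6 throughout.
#' @export
mobilenet_v2_spec <- function(num_classes = 25, input_size = 224, seed = 1L) {
  model_spec(character(0), r = 4, num_classes = num_classes, use_eca = FALSE,
             use_hardswish = FALSE, input_size = input_size, seed = seed)
}

#' Improved bottleneck block with RepMLP feature extraction
#'
#' Point-by-point channel REDUCTION by factor `r` (1 x 1 conv + BN +
#' Hardswish or ReLU6), an optional parameter-free 2 x 2 average-pool
#' downsample (FC partitions cannot stride), RepMLP feature extraction at
#' the reduced width, then a 1 x 1 conv + BN restoring the stage's channel
#' count.  Residual connection when shapes allow; no activation after the
#' restoring projection.
#'
#' @param in_channels,out_channels Block input/output channels.
#' @param r Reduction factor; `in_channels` must be divisible by it.
#' @param resolution Input feature-map side length (decides the RepMLP
#'   partitioning via [repmlp_calibration()]).
#' @param downsample Halve the resolution (first block of a stride-2
#'   stage)?
#' @param activation `"hardswish"` or `"relu6"` after the reduction conv.
#' @return A bottleneck-RepMLP block layer.
#' @export
nn_bottleneck_repmlp <- function(in_channels, out_channels, r = 4,
                                 resolution, downsample = FALSE,
                                 activation = "hardswish") {
  if (in_channels %% r != 0)
    stop("input channels (", in_channels, ") not divisible by r = ", r)
  mid <- in_channels / r
  res <- if (downsample) resolution / 2 else resolution
  cal <- repmlp_calibration(mid, res)
  layers <- list(
    reduce_conv = nn_conv2d(in_channels, mid, 1),
    reduce_bn = nn_batchnorm2d(mid),
    reduce_act = nn_activation(activation))
  if (downsample) layers$pool <- nn_avgpool2x2()
  layers$repmlp <- nn_repmlp(mid, cal$h, cal$w, groups = cal$groups,
                             rho = cal$rho, kernels = cal$kernels)
  layers$expand_conv <- nn_conv2d(mid, out_channels, 1)
  layers$expand_bn <- nn_batchnorm2d(out_channels)
  new_layer("bottleneck_repmlp", list(
    in_channels = in_channels, out_channels = out_channels, r = r,
    resolution = resolution, downsample = downsample,
    use_residual = !downsample && in_channels == out_channels,
    layers = layers))
}

#' @export
layer_forward.nn_bottleneck_repmlp <- function(layer, x, training = FALSE) {
  body <- nn_sequential(layer$layers)
  rs <- layer_forward(body, x, training)
  out <- if (layer$use_residual) rs$out + x else rs$out
  list(out = out, cache = rs$cache)
}

#' @export
layer_backward.nn_bottleneck_repmlp <- function(layer, cache, gout) {
  body <- nn_sequential(layer$layers)
  r <- layer_backward(body, cache, gout)
  gin <- if (layer$use_residual) r$gin + gout else r$gin
  list(gin = gin, grads = r$grads)
}

#' Bottleneck-RepMLP forward pass
#' @param x Feature map.
#' @param block Layer from [nn_bottleneck_repmlp()].
#' @param training Batch-norm mode.
#' @return Output feature map.
#' @export
bottleneck_repmlp_forward <- function(x, block, training = FALSE) {
  layer_forward(block, x, training)$out
}

## ---- full model -------------------------------------------------------

#' Build a network from a model specification
#'
#' Stem 3 x 3 stride-2 conv to 32 channels; seven bottleneck stages per the
#' backbone table (RepMLP bottlenecks where the spec says so, standard
#' inverted residuals elsewhere); optional ECA after every block instance;
#' 1 x 1 conv to 1,280 channels; global average pooling; linear classifier.
#'
#' @param spec A [model_spec()].
#' @return A model object (class `repmlp_model`).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  withr::with_seed(spec$seed, build_model_impl(spec))
}

build_model_impl <- function(spec) {
  stages <- backbone_stages()
  layers <- list(
    stem = nn_sequential(list(conv = nn_conv2d(3, 32, 3, stride = 2, padding = 1),
                              bn = nn_batchnorm2d(32),
                              act = nn_activation("relu6"))))
  res <- spec$input_size / 2
  in_ch <- 32
  stage_out_shapes <- list()
  for (sn in names(stages)) {
    st <- stages[[sn]]
    use_rep <- sn %in% spec$repmlp_stages
    for (bi in seq_len(st$n)) {
      stride <- if (bi == 1) st$s else 1L
      nm <- sprintf("%s_%d", sn, bi)
      if (use_rep) {
        blk <- nn_bottleneck_repmlp(
          in_ch, st$c, r = spec$r, resolution = res,
          downsample = stride == 2,
          activation = if (spec$use_hardswish) "hardswish" else "relu6")
      } else {
        blk <- nn_inverted_residual(in_ch, st$c, expand_t = st$t,
                                    stride = stride, activation = "relu6")
      }
      # zero-gamma on the last BN of residual blocks: each such block starts
      # as the identity, which conditions short high-lr runs much better
      if (blk$use_residual) {
        last_bn <- if (inherits(blk, "nn_bottleneck_repmlp")) "expand_bn" else "proj_bn"
        blk$layers[[last_bn]]$gamma[] <- 0
      }
      layers[[nm]] <- blk
      if (spec$use_eca) layers[[paste0(nm, "_eca")]] <- nn_eca(st$c)
      if (stride == 2) res <- res / 2
      in_ch <- st$c
    }
    stage_out_shapes[[sn]] <- c(in_ch, res, res)
  }
  layers$head_conv <- nn_conv2d(in_ch, 1280, 1)
  layers$head_bn <- nn_batchnorm2d(1280)
  layers$head_act <- nn_activation("relu6")
  layers$pool <- nn_global_pool()
  layers$classifier <- nn_linear(1280, spec$num_classes, bias = TRUE)
  structure(list(kind = "model", spec = spec, layers = layers,
                 stage_out_shapes = stage_out_shapes),
            class = c("repmlp_model", "nn_sequential", "nn_layer"))
}

#' Model forward pass
#'
#' @param model A built model.
#' @param x Feature map `(N, 3, H, W)`.
#' @param training Batch-norm mode.
#' @return Logits matrix `(N, num_classes)`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  layer_forward(model, x, training)$out
}

#' Per-stage output shapes of a forward pass
#'
#' Runs `x` through the model and records the output shape of every
#' top-level layer; used to check the bookkeeping of the printed network
#' table.
#'
#' @param model A built model.
#' @param x Input feature map.
#' @return Named list of dimension vectors.
#' @export
model_shape_trace <- function(model, x) {
  shapes <- list()
  for (nm in names(model$layers)) {
    x <- layer_forward(model$layers[[nm]], x)$out
    shapes[[nm]] <- dim(x) %||% c(nrow(x), ncol(x))
  }
  shapes
}

#' @describeIn reparameterize Replace every training-form RepMLP inside the
#'   model by its deployed form; all other layers are untouched.
#' @export
reparameterize.repmlp_model <- function(object, ...) {
  object$layers <- lapply(object$layers, function(l) {
    if (inherits(l, "nn_bottleneck_repmlp")) {
      l$layers$repmlp <- reparameterize(l$layers$repmlp)
    }
    l
  })
  object
}

## ---- weight archive ---------------------------------------------------

#' Save model weights as a flat key -> array archive
#'
#' Keys follow the `stage.block.layer.param` dotted schema from
#' [flatten_params()]; batch-norm running statistics are stored under
#' `...stats.mean` / `...stats.var` keys so the archive round-trips
#' inference behaviour exactly.
#'
#' @param model A built model.
#' @param path File path (RDS).
#' @return `path`, invisibly.
#' @export
save_weights <- function(model, path) {
  flat <- flatten_params(layer_params(model))
  flat <- c(flat, flatten_params(collect_bn_stats(model$layers)))
  saveRDS(flat, path)
  invisible(path)
}

#' Load a weight archive into a model of matching architecture
#'
#' @param model A built model (same spec as the saved one).
#' @param path Archive path from [save_weights()].
#' @return The model with restored parameters and BN statistics.
#' @export
load_weights <- function(model, path) {
  flat <- readRDS(path)
  stats_keys <- grepl("\\.stats\\.(mean|var)$", names(flat))
  model <- layer_set_params(model, unflatten_params(flat[!stats_keys]))
  restore_bn_stats(model$layers, unflatten_params(flat[stats_keys]))
  model
}

collect_bn_stats <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (inherits(l, "nn_batchnorm2d")) {
      out[[nm]] <- list(stats = list(mean = l$stats$mean, var = l$stats$var))
    } else if (!is.null(l$layers)) {
      sub <- collect_bn_stats(l$layers)
      if (length(sub)) out[[nm]] <- sub
    }
  }
  out
}

restore_bn_stats <- function(layers, stats) {
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (inherits(l, "nn_batchnorm2d") && !is.null(stats[[nm]]$stats)) {
      l$stats$mean <- as.numeric(stats[[nm]]$stats$mean)
      l$stats$var <- as.numeric(stats[[nm]]$stats$var)
    } else if (!is.null(l$layers) && !is.null(stats[[nm]])) {
      restore_bn_stats(l$layers, stats[[nm]])
    }
  }
  invisible(NULL)
}
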