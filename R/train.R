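# Training loop (SGD with momentum, cosine-annealed learning rate,
# cross-entropy), evaluation metrics, and an informational inference
# timer.

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi * t / T)) / 2`, so the
#' schedule starts at `lr_max` and ends at `lr_min` after `T` steps.
#'
#' @param t Current step (0 <= t <= T).
#' @param T Total steps (> 0).
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate at step `t`.
#' @export
cosine_lr <- function(t, T, lr_max = 0.1, lr_min = 1e-4) {
  if (T <= 0) stop("T must be positive")
  if (t < 0 || t > T) stop("t must lie in [0, T]")
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))
}

#' Training configuration
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs; the cosine schedule is stepped per
#'   epoch (`T = epochs`).
#' @param lr_max,lr_min Cosine schedule endpoints.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty added to gradients.
#' @param clip_norm Global gradient-norm ceiling (Inf disables); keeps the
#'   first steps of short runs stable.
#' @param warmup_epochs Epochs of linear learning-rate ramp (from
#'   `lr_max / 10`) before the cosine schedule begins.
#' @param swa_epochs Average the weights over the steps of the last
#'   `swa_epochs` epochs (0 disables).  Tail averaging smooths the noise of
#'   the final SGD steps; combined with the batch-norm recalibration pass
#'   it stabilizes short runs considerably.
#' @param seed Shuffling/initialization seed for the run.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16, epochs = 5, lr_max = 0.1,
                         lr_min = 1e-4, momentum = 0.9, weight_decay = 4e-5,
                         clip_norm = 5, warmup_epochs = 0, swa_epochs = 0,
                         seed = 1L) {
  stopifnot(lr_max > lr_min, lr_min > 0, batch_size >= 1, epochs >= 1,
            clip_norm > 0, warmup_epochs >= 0, warmup_epochs < epochs,
            swa_epochs >= 0, swa_epochs <= epochs)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_max = lr_max,
                 lr_min = lr_min, momentum = momentum,
                 weight_decay = weight_decay, clip_norm = clip_norm,
                 warmup_epochs = as.integer(warmup_epochs),
                 swa_epochs = as.integer(swa_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

schedule_lr <- function(epoch, config) {
  w <- config$warmup_epochs %||% 0L
  if (epoch <= w)
    return(config$lr_max * (0.1 + 0.9 * (epoch - 1) / w))
  cosine_lr(epoch - 1 - w, config$epochs - w, config$lr_max, config$lr_min)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and logits gradient; y is 0-based class ids
ce_loss_grad <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n)
}

#' Train a model with SGD + cosine annealing
#'
#' Cross-entropy objective, mini-batch SGD with momentum and weight decay,
#' learning rate annealed per epoch from `lr_max` to `lr_min`.
#' Deterministic given the config seed (single-threaded BLAS assumed).
#'
#' @param model A built model.
#' @param data List with `x` (N x 3 x H x W array, normalized) and `y`
#'   (0-based integer labels), e.g. from [load_dataset()].
#' @param config A [train_config()].
#' @param eval_data Optional held-out list like `data`; accuracy recorded
#'   per epoch when supplied.
#' @param recalibrate Refresh the batch-norm running statistics with one
#'   extra pass over the training data after the last epoch (see
#'   [recalibrate_bn()]).
#' @param verbose Print one line per epoch?
#' @return List with the trained `model` and a `history` tibble (epoch,
#'   lr, loss, and optionally test accuracy).
#' @export
train_model <- function(model, data, config = train_config(),
                        eval_data = NULL, recalibrate = TRUE,
                        verbose = FALSE) {
  n <- dim(data$x)[1]
  if (n == 0) stop("empty training set")
  params <- flatten_params(layer_params(model))
  velocity <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  history <- list()
  swa_from <- config$epochs - (config$swa_epochs %||% 0L) + 1L
  swa_sum <- NULL
  swa_n <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- schedule_lr(epoch, config)
      ord <- sample(n)
      ep_loss <- 0; n_batches <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- data$x[idx, , , , drop = FALSE]
        yb <- data$y[idx]
        fw <- layer_forward(model, xb, training = TRUE)
        lg <- ce_loss_grad(fw$out, yb)
        bw <- layer_backward(model, fw$cache, lg$grad)
        grads <- flatten_params(bw$grads)
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (is.finite(config$clip_norm) && gnorm > config$clip_norm)
          grads <- lapply(grads, function(g) g * config$clip_norm / gnorm)
        params <- flatten_params(layer_params(model))
        for (k in names(params)) {
          g <- grads[[k]] + config$weight_decay * params[[k]]
          velocity[[k]] <- config$momentum * velocity[[k]] + g
          params[[k]] <- params[[k]] - lr * velocity[[k]]
        }
        model <- layer_set_params(model, unflatten_params(params))
        if (epoch >= swa_from) {
          swa_sum <- if (is.null(swa_sum)) params
                     else Map(`+`, swa_sum, params)
          swa_n <- swa_n + 1L
        }
        ep_loss <- ep_loss + lg$loss
        n_batches <- n_batches + 1
      }
      row <- list(epoch = epoch, lr = lr, loss = ep_loss / n_batches)
      if (!is.null(eval_data)) {
        row$test_accuracy <- evaluate_model(model, eval_data)$accuracy
      }
      if (verbose)
        cat(sprintf("epoch %d lr %.4f loss %.4f %s\n", epoch, lr, row$loss,
                    if (!is.null(row$test_accuracy))
                      sprintf("test acc %.1f%%", row$test_accuracy) else ""))
      history[[epoch]] <- tibble::as_tibble(row)
    }
    if (swa_n > 0) {
      model <- layer_set_params(model, unflatten_params(
        lapply(swa_sum, function(p) p / swa_n)))
    }
    if (recalibrate) recalibrate_bn(model, data$x, config$batch_size)
  })
  list(model = model, history = do.call(rbind, history))
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean/variance by the average
#' of its batch statistics over one pass of the supplied data.  Short
#' training runs leave the momentum-tracked running statistics lagging the
#' trained weights; a recalibration pass aligns inference-mode behaviour
#' with the final weights (common deployment practice for re-parameterized
#' and weight-averaged models).
#'
#' @param model A built model (BN statistics are updated in place).
#' @param x Input array `N x 3 x H x W` (typically the training images).
#' @param batch_size Pass batch size.
#' @return The model, invisibly.
#' @export
recalibrate_bn <- function(model, x, batch_size = 32) {
  n <- dim(x)[1]
  # shuffle (deterministically) so batches are class-mixed: with
  # class-ordered data the average of within-batch variances would
  # underestimate the population variance
  ord <- withr::with_seed(1L, sample(n))
  starts <- seq(1, n, by = batch_size)
  # with momentum 1/i at pass i the running buffers hold the exact average
  # of the per-batch statistics after the last pass; the stats environments
  # are shared between the momentum-modified copy and `model`
  for (i in seq_along(starts)) {
    probe <- set_bn_momentum(model, 1 / i)
    idx <- ord[starts[i]:min(starts[i] + batch_size - 1, n)]
    invisible(layer_forward(probe, x[idx, , , , drop = FALSE], training = TRUE))
  }
  invisible(model)
}

set_bn_momentum <- function(layer, m) {
  if (inherits(layer, "nn_batchnorm2d")) {
    layer$momentum <- m
  } else if (!is.null(layer$layers)) {
    layer$layers <- lapply(layer$layers, set_bn_momentum, m = m)
  }
  layer
}

#' Evaluate a classifier
#'
#' Confusion matrix (rows = true class, columns = predicted), overall
#' accuracy, and macro-averaged recall and precision in percent.  Classes
#' absent from the test data are excluded from the macro averages with a
#' warning.
#'
#' @param model A built (or deployed) model.
#' @param data List with `x` and 0-based `y`.
#' @param batch_size Forward-pass batch size.
#' @return List with `accuracy`, `recall`, `precision` (percent),
#'   `confusion`, and per-class vectors.
#' @export
evaluate_model <- function(model, data, batch_size = 32) {
  n <- dim(data$x)[1]
  if (n == 0) stop("empty evaluation set")
  k <- model$spec$num_classes
  pred <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits <- model_forward(model, data$x[idx, , , , drop = FALSE])
    pred[idx] <- max.col(logits, ties.method = "first") - 1L
  }
  metrics_from_predictions(data$y, pred, k)
}

#' Classification metrics from labels and predictions
#'
#' @param y True 0-based labels.
#' @param pred Predicted 0-based labels.
#' @param k Number of classes.
#' @return List with `accuracy`, `recall`, `precision` (macro, percent),
#'   `confusion`, `per_class_recall`, `per_class_precision`.
#' @export
metrics_from_predictions <- function(y, pred, k) {
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(y))
    confusion[y[i] + 1L, pred[i] + 1L] <- confusion[y[i] + 1L, pred[i] + 1L] + 1L
  present <- rowSums(confusion) > 0
  if (!all(present))
    warning("classes absent from the data are excluded from macro averages: ",
            paste(which(!present) - 1L, collapse = ", "))
  rec <- diag(confusion) / rowSums(confusion)
  predicted <- colSums(confusion) > 0
  prec <- diag(confusion) / colSums(confusion)
  list(accuracy = 100 * sum(diag(confusion)) / sum(confusion),
       recall = 100 * mean(rec[present]),
       precision = 100 * mean(prec[present & predicted]),
       confusion = confusion,
       per_class_recall = 100 * rec,
       per_class_precision = 100 * prec)
}

#' Time per-image inference (informational)
#'
#' Mean per-image forward latency over `repeats` passes on `n_images`
#' synthetic inputs.  Hardware-dependent; reported for orientation only.
#'
#' @param model A built model.
#' @param n_images Number of probe images.
#' @param repeats Timed passes (>= 1).
#' @param input_size Square input side.
#' @return List with `ms_per_image` and the raw per-pass timings.
#' @export
bench_inference <- function(model, n_images = 4, repeats = 3,
                            input_size = model$spec$input_size) {
  if (repeats < 1) stop("repeats must be >= 1")
  x <- array(rnorm(n_images * 3 * input_size^2),
             c(n_images, 3, input_size, input_size))
  times <- vapply(seq_len(repeats), function(i) {
    unname(system.time(model_forward(model, x))["elapsed"])
  }, numeric(1))
  list(ms_per_image = 1000 * mean(times) / n_images, seconds = times)
}

#' Compare training-form and deployed-form inference speed
#'
#' @param model A training-form model containing RepMLP blocks.
#' @param n_images,repeats,input_size As in [bench_inference()].
#' @return Tibble with one row per form (`model`, `form`, `ms`,
#'   `relative_change`): the deployed form's relative latency change vs
#'   the training form (negative = faster).
#' @export
bench_reparam <- function(model, n_images = 4, repeats = 3,
                          input_size = model$spec$input_size) {
  t1 <- bench_inference(model, n_images, repeats, input_size)$ms_per_image
  t2 <- bench_inference(reparameterize(model), n_images, repeats,
                        input_size)$ms_per_image
  tibble::tibble(model = "mobilenet_repmlp",
                 form = c("training", "deployed"),
                 ms = c(t1, t2),
                 relative_change = c(0, (t2 - t1) / t1))
}
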