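# Synthetic leaf-disease imagery: a procedural stand-in for controlled-
# background leaf photo collections.  Each class is a crop/condition pair
# with its own leaf hue and lesion appearance (color, count, size, blur),
# rendered as an elliptical leaf on a plain background.  Every image is a
# deterministic function of (class model, seed).

#' Class appearance models for the synthetic leaf set
#'
#' Builds `n_classes` class models over five crops (distinct leaf hues) and
#' five conditions per crop (healthy plus four lesion phenotypes differing
#' in lesion color, count, size and blur).  Any two classes differ in leaf
#' hue or at least one lesion parameter.
#'
#' @param n_classes Number of classes (default 25 = 5 crops x 5
#'   conditions; smaller values take the first classes of the grid).
#' @return List of `leaf_class_model` objects; class ids are `0:(n-1)`.
#' @export
leaf_class_models <- function(n_classes = 25) {
  stopifnot(n_classes >= 1, n_classes <= 25)
  crops <- data.frame(
    name = c("apple", "corn", "grape", "potato", "tomato"),
    hue = c(0.30, 0.22, 0.36, 0.28, 0.33),        # leaf green, per crop
    sat = c(0.65, 0.55, 0.70, 0.60, 0.68))
  conditions <- list(
    list(name = "healthy", count = c(0, 0), color = c(0, 0, 0), size = 0, blur = 0),
    list(name = "dark_spot", count = c(4, 9), color = c(0.25, 0.15, 0.08),
         size = 0.045, blur = 1),
    list(name = "rust", count = c(10, 22), color = c(0.72, 0.42, 0.12),
         size = 0.025, blur = 0),
    list(name = "blight", count = c(2, 4), color = c(0.45, 0.38, 0.20),
         size = 0.12, blur = 2),
    list(name = "mosaic", count = c(6, 12), color = c(0.85, 0.85, 0.35),
         size = 0.07, blur = 3))
  models <- list()
  for (ci in seq_len(5)) for (di in seq_len(5)) {
    id <- (ci - 1) * 5 + di - 1
    if (id >= n_classes) next
    cond <- conditions[[di]]
    models[[id + 1]] <- structure(list(
      class_id = id,
      label = paste(crops$name[ci], cond$name, sep = "_"),
      leaf_hue = crops$hue[ci], leaf_sat = crops$sat[ci],
      lesion_color = cond$color, lesion_count = cond$count,
      lesion_size = cond$size, lesion_blur = cond$blur,
      background = c(0.82, 0.80, 0.76)), class = "leaf_class_model")
  }
  models
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

#' Render one synthetic leaf image
#'
#' Deterministic in `(cls, seed)`: identical calls give byte-identical
#' images.  The image is an elliptical leaf (class-specific hue with mild
#' per-image hue/size jitter and a midrib) on a plain background, with
#' lesions drawn as blurred ellipses per the class model.
#'
#' @param cls A `leaf_class_model` from [leaf_class_models()].
#' @param seed Integer seed for the per-image variation.
#' @param size Square image side in pixels (>= 32).
#' @return `size x size x 3` array of integers in 0..255 (RGB).
#' @export
generate_leaf_image <- function(cls, seed, size = 224) {
  stopifnot(inherits(cls, "leaf_class_model"), size >= 32)
  withr::with_seed(as.integer(seed), {
    img <- array(rep(cls$background, each = size * size), c(size, size, 3))
    cx <- size / 2 + runif(1, -0.04, 0.04) * size
    cy <- size / 2 + runif(1, -0.04, 0.04) * size
    ax <- size * runif(1, 0.30, 0.38)
    ay <- size * runif(1, 0.36, 0.44)
    theta <- runif(1, -0.35, 0.35)
    hue <- cls$leaf_hue + runif(1, -0.02, 0.02)
    base_rgb <- hsv_to_rgb(hue, cls$leaf_sat, runif(1, 0.45, 0.6))
    xs <- matrix(rep(seq_len(size), size), size, size)        # row = y
    ys <- t(xs)
    rx <- (ys - cx) * cos(theta) + (xs - cy) * sin(theta)
    ry <- -(ys - cx) * sin(theta) + (xs - cy) * cos(theta)
    inside <- (rx / ax)^2 + (ry / ay)^2 <= 1
    shade <- 1 - 0.25 * abs(rx / ax)                          # simple shading
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- base_rgb[ch] * shade[inside]
      img[, , ch] <- plane
    }
    midrib <- inside & abs(rx) < size * 0.008
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[midrib] <- base_rgb[ch] * 0.6
      img[, , ch] <- plane
    }
    n_les <- if (cls$lesion_count[2] > 0)
      sample(cls$lesion_count[1]:cls$lesion_count[2], 1) else 0
    if (n_les > 0) {
      in_idx <- which(inside, arr.ind = TRUE)
      for (li in seq_len(n_les)) {
        ctr <- in_idx[sample(nrow(in_idx), 1), ]
        r <- size * cls$lesion_size * runif(1, 0.6, 1.4)
        ecc <- runif(1, 0.6, 1)
        d2 <- ((xs - ctr[1]) / r)^2 + ((ys - ctr[2]) / (r * ecc))^2
        soft <- pmax(0, 1 - d2)^(1 + cls$lesion_blur / 2)
        soft[!inside] <- 0
        col <- cls$lesion_color * runif(1, 0.8, 1.2)
        for (ch in 1:3)
          img[, , ch] <- img[, , ch] * (1 - soft) + col[ch] * soft
      }
    }
    noise <- array(rnorm(size * size * 3, 0, 0.012), dim(img))
    array(as.integer(pmin(255, pmax(0, round((img + noise) * 255)))), dim(img))
  })
}

## ---- augmentation -----------------------------------------------------

#' Augmentation operation descriptor
#'
#' @param kind One of `"flip"` (vertical), `"mirror"` (horizontal),
#'   `"rotate"` (90-degree steps), `"brightness"`, `"contrast"`,
#'   `"noise"`.
#' @param magnitude Operation strength: rotation steps (1-3) for
#'   `"rotate"`; multiplicative factor for `"brightness"`/`"contrast"`
#'   (1 is the identity); noise standard deviation in gray levels for
#'   `"noise"`.
#' @param seed Seed for stochastic ops (`"noise"`).
#' @return An `augment_op`.
#' @export
augment_op <- function(kind, magnitude = 1, seed = 0L) {
  kinds <- c("flip", "mirror", "rotate", "brightness", "contrast", "noise")
  if (!kind %in% kinds) stop("unknown augmentation op: ", kind)
  if (kind %in% c("brightness", "contrast") && (magnitude < 0.3 || magnitude > 3))
    stop("brightness/contrast magnitude outside the safe range [0.3, 3]")
  if (kind == "noise" && (magnitude < 0 || magnitude > 30))
    stop("noise magnitude outside the safe range [0, 30] gray levels")
  structure(list(kind = kind, magnitude = magnitude, seed = as.integer(seed)),
            class = "augment_op")
}

apply_one_op <- function(img, op) {
  switch(op$kind,
    flip = img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
    mirror = img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
    rotate = {
      k <- ((op$magnitude - 1) %% 3) + 1
      out <- img
      for (i in seq_len(k))
        out <- aperm(out, c(2, 1, 3))[rev(seq_len(dim(out)[2])), , , drop = FALSE]
      out
    },
    brightness = pmin(pmax(round(img * op$magnitude), 0), 255),
    contrast = {
      m <- mean(img)
      pmin(pmax(round(m + (img - m) * op$magnitude), 0), 255)
    },
    noise = withr::with_seed(op$seed, {
      pmin(pmax(round(img + rnorm(length(img), 0, op$magnitude)), 0), 255)
    }),
    stop("unknown augmentation op: ", op$kind))
}

#' Apply a sequence of augmentation ops to an image
#'
#' Deterministic given the ops (and their seeds); shape and 0..255 integer
#' range are preserved.
#'
#' @param image `H x W x 3` integer array.
#' @param ops List of [augment_op()] objects, applied in order.
#' @return Augmented image, same shape and dtype.
#' @export
augment <- function(image, ops) {
  for (op in ops) {
    if (!inherits(op, "augment_op")) stop("ops must be augment_op objects")
    image <- apply_one_op(image, op)
  }
  array(as.integer(image), dim(image))
}

random_op_combo <- function() {
  picks <- sample(c("flip", "mirror", "rotate", "brightness", "contrast", "noise"),
                  sample(1:3, 1))
  lapply(picks, function(k) {
    switch(k,
      flip = augment_op("flip"),
      mirror = augment_op("mirror"),
      rotate = augment_op("rotate", sample(1:3, 1)),
      brightness = augment_op("brightness", runif(1, 0.7, 1.3)),
      contrast = augment_op("contrast", runif(1, 0.7, 1.3)),
      noise = augment_op("noise", runif(1, 3, 8), seed = sample.int(1e6, 1)))
  })
}

## ---- manifests --------------------------------------------------------

new_manifest <- function(path, class, split, provenance, source, ops, seed) {
  tibble::tibble(path = path, class = as.integer(class), split = split,
                 provenance = provenance, source = source, ops = ops,
                 seed = as.integer(seed))
}

#' Build a manifest of original synthetic images
#'
#' Records only; use [materialize_manifest()] to render PNGs.
#'
#' @param classes List from [leaf_class_models()] (or a subset).
#' @param per_class Number of original images per class (scalar or
#'   vector).
#' @param seed Base seed; image seeds are derived deterministically.
#' @param dir Directory prefix recorded in the paths.
#' @return A manifest tibble (columns `path`, `class`, `split`,
#'   `provenance`, `source`, `ops`, `seed`).
#' @export
make_manifest <- function(classes, per_class, seed = 1L, dir = "images") {
  n_cls <- length(classes)
  per_class <- rep_len(per_class, n_cls)
  rows <- list()
  for (i in seq_len(n_cls)) {
    id <- classes[[i]]$class_id
    seeds <- seed * 100000L + id * 10000L + seq_len(per_class[i])
    rows[[i]] <- new_manifest(
      path = file.path(dir, sprintf("c%02d_%05d.png", id, seq_len(per_class[i]))),
      class = id, split = NA_character_, provenance = "original",
      source = NA_character_, ops = NA_character_, seed = seeds)
  }
  do.call(rbind, rows)
}

#' Assign train/test splits to a manifest
#'
#' Stratified per class at the given train:test ratio; deterministic given
#' the seed.  A class with fewer than 2 originals is assigned entirely to
#' the training split with a warning.
#'
#' @param manifest Manifest of original records.
#' @param ratio Train:test ratio as a length-2 vector (default `c(4, 1)`).
#' @param seed Split seed.
#' @return The manifest with `split` filled in.
#' @export
split_dataset <- function(manifest, ratio = c(4, 1), seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  test_frac <- ratio[2] / sum(ratio)
  withr::with_seed(as.integer(seed), {
    for (id in unique(manifest$class)) {
      idx <- which(manifest$class == id & manifest$provenance == "original")
      if (length(idx) < 2) {
        warning("class ", id, " has fewer than 2 originals; assigning all to train")
        manifest$split[idx] <- "train"
        next
      }
      n_test <- round(length(idx) * test_frac)
      test_idx <- idx[sample.int(length(idx), n_test)]
      manifest$split[idx] <- ifelse(idx %in% test_idx, "test", "train")
    }
  })
  manifest
}

#' Balance classes to target counts by augmentation (or subsampling)
#'
#' Brings the chosen split of each class to its per-class target.  Classes
#' below target are padded with augmented records, each referencing a
#' randomly chosen record of the same class and split (never the other
#' split, so no train/test leakage) and carrying the sampled op
#' combination.  Classes above target are subsampled down to it
#' (augmented records are dropped first) — curated collections are often
#' so imbalanced that a flat target sits below the largest classes' split
#' counts.
#'
#' @param manifest Manifest with splits assigned.
#' @param per_class_target Scalar or named/ordered vector of per-class
#'   targets.
#' @param split Which split to pad (`"train"` or `"test"`).
#' @param seed Sampling seed.
#' @param op_sampler Function returning a list of [augment_op()]s for one
#'   new record (default: random combinations of flip/mirror/rotate/
#'   color/noise).
#' @return The manifest with augmented records appended.
#' @export
balance_by_augmentation <- function(manifest, per_class_target,
                                    split = "train", seed = 1L,
                                    op_sampler = random_op_combo) {
  ids <- sort(unique(manifest$class))
  targets <- rep_len(per_class_target, length(ids))
  withr::with_seed(as.integer(seed), {
    add <- list()
    drop_rows <- integer(0)
    for (k in seq_along(ids)) {
      id <- ids[k]
      idx <- which(manifest$class == id & manifest$split == split)
      if (length(idx) == 0) stop("class ", id, " has no records in split ", split)
      cur <- length(idx)
      if (targets[k] < cur) {
        # subsample down: drop augmented records first, then originals that
        # no remaining augmented record references
        n_drop <- cur - targets[k]
        aug_idx <- idx[manifest$provenance[idx] == "augmented"]
        take <- aug_idx[sample.int(length(aug_idx), min(n_drop, length(aug_idx)))]
        n_drop <- n_drop - length(take)
        if (n_drop > 0) {
          kept_aug <- setdiff(which(manifest$provenance == "augmented"), take)
          referenced <- manifest$path[idx] %in% manifest$source[kept_aug]
          free <- idx[manifest$provenance[idx] == "original" & !referenced]
          if (length(free) < n_drop)
            stop("cannot subsample class ", id,
                 ": too many originals are referenced by augmented records")
          take <- c(take, free[sample.int(length(free), n_drop)])
        }
        drop_rows <- c(drop_rows, take)
        next
      }
      n_new <- targets[k] - cur
      if (n_new == 0) next
      src_idx <- idx[sample.int(length(idx), n_new, replace = TRUE)]
      ops <- vapply(seq_len(n_new),
                    function(i) serialize_ops(op_sampler()), character(1))
      add[[length(add) + 1]] <- new_manifest(
        path = sprintf("%s_aug%05d.png",
                       sub("\\.png$", "", manifest$path[src_idx]),
                       seq_len(n_new)),
        class = id, split = split, provenance = "augmented",
        source = manifest$path[src_idx], ops = ops,
        seed = sample.int(.Machine$integer.max %/% 2, n_new))
    }
  })
  if (length(drop_rows)) manifest <- manifest[-drop_rows, ]
  if (length(add)) manifest <- rbind(manifest, do.call(rbind, add))
  manifest
}

serialize_ops <- function(ops) {
  paste(vapply(ops, function(o)
    sprintf("%s:%g:%d", o$kind, o$magnitude, o$seed), character(1)),
    collapse = ";")
}

deserialize_ops <- function(s) {
  if (is.na(s) || s == "") return(list())
  lapply(strsplit(s, ";", fixed = TRUE)[[1]], function(tok) {
    p <- strsplit(tok, ":", fixed = TRUE)[[1]]
    augment_op(p[1], as.numeric(p[2]), as.integer(p[3]))
  })
}

#' Per-class image counts of the PlantVillage subset used for comparison
#'
#' The 25 leaf categories (five crops with three or more recorded states)
#' with their original, expanded-training and test sheet counts.  Used as
#' balancing targets so manifest arithmetic reproduces the published
#' totals (30,644 / 37,572 / 10,359).
#'
#' @return Tibble with columns `category`, `original`, `train`, `test`.
#' @export
plantvillage_counts <- function() {
  tibble::tibble(
    category = c("Apple scab", "Apple black rot", "Apple rust", "Apple healthy",
                 "Corn gray spot", "Corn rust", "Corn healthy", "Corn leaf blight",
                 "Grape black rot", "Grape black measles", "Grape healthy",
                 "Grape leaf blight", "Potato early blight", "Potato healthy",
                 "Potato late blight", "Tomato health", "Tomato spot blight",
                 "Tomato two spotted spider mite", "Tomato late blight",
                 "Tomato leaf mold", "Tomato bacterial spot", "Tomato target spot",
                 "Tomato early blight", "Tomato mosaic virus", "Tomato yellow leaf"),
    original = c(630, 621, 275, 1645, 513, 1192, 1162, 985, 1180, 1383, 423,
                 1076, 1000, 152, 1000, 1591, 1000, 1676, 1909, 952, 2127,
                 1404, 1000, 373, 5375),
    train = c(1512, 1491, 1510, 1495, 1505, 1502, 1501, 1506, 1500, 1507,
              1508, 1506, 1500, 1464, 1500, 1503, 1517, 1506, 1528, 1502,
              1500, 1514, 1500, 1495, 1500),
    test = c(437, 418, 416, 404, 408, 409, 402, 394, 436, 424, 402, 415,
             400, 420, 400, 406, 401, 405, 401, 380, 425, 487, 425, 444, 400))
}

## ---- rendering & loading ---------------------------------------------

#' Render a manifest to PNG files
#'
#' Originals are generated from their class model and recorded seed;
#' augmented records are rendered by augmenting their source image with
#' the recorded ops.  Paths are created under `root`.
#'
#' @param manifest Manifest tibble.
#' @param root Output directory.
#' @param classes Class models (must cover the manifest's class ids).
#' @param size Image side in pixels.
#' @return The manifest, invisibly.
#' @export
materialize_manifest <- function(manifest, root, classes, size = 224) {
  by_id <- list()
  for (cm in classes) by_id[[as.character(cm$class_id)]] <- cm
  cache <- new.env(parent = emptyenv())
  render <- function(i) {
    p <- manifest$path[i]
    if (!is.null(cache[[p]])) return(cache[[p]])
    img <- if (manifest$provenance[i] == "original") {
      generate_leaf_image(by_id[[as.character(manifest$class[i])]],
                          manifest$seed[i], size)
    } else {
      src <- which(manifest$path == manifest$source[i])[1]
      if (is.na(src)) stop("augmented record references missing source: ",
                           manifest$source[i])
      augment(render(src), deserialize_ops(manifest$ops[i]))
    }
    cache[[p]] <- img
    img
  }
  for (i in seq_len(nrow(manifest))) {
    img <- render(i)
    out <- file.path(root, manifest$path[i])
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(img / 255, out)
  }
  invisible(manifest)
}

#' Load a manifest split as a training-ready dataset
#'
#' Renders images in memory (no files needed) and normalizes pixels to
#' `[-1, 1]` in NCHW layout.
#'
#' @param manifest Manifest tibble.
#' @param classes Class models.
#' @param split `"train"` or `"test"`.
#' @param size Image side in pixels.
#' @return List with `x` (array `N x 3 x size x size`) and `y` (integer
#'   class ids, 0-based).
#' @export
load_dataset <- function(manifest, classes, split = "train", size = 64) {
  rows <- which(manifest$split == split)
  by_id <- list()
  for (cm in classes) by_id[[as.character(cm$class_id)]] <- cm
  x <- array(0, c(length(rows), 3, size, size))
  y <- integer(length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    img <- if (manifest$provenance[i] == "original") {
      generate_leaf_image(by_id[[as.character(manifest$class[i])]],
                          manifest$seed[i], size)
    } else {
      src <- which(manifest$path == manifest$source[i])[1]
      base <- generate_leaf_image(by_id[[as.character(manifest$class[src])]],
                                  manifest$seed[src], size)
      augment(base, deserialize_ops(manifest$ops[i]))
    }
    x[j, , , ] <- aperm(img, c(3, 1, 2)) / 127.5 - 1
    y[j] <- manifest$class[i]
  }
  list(x = x, y = y)
}
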