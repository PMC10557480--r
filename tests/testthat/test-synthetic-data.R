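test_that("leaf generator is deterministic with the documented shape and range", {
  cls <- leaf_class_models(25)
  expect_length(cls, 25)
  expect_length(unique(vapply(cls, `[[`, "", "label")), 25)
  img1 <- generate_leaf_image(cls[[3]], seed = 7, size = 64)
  img2 <- generate_leaf_image(cls[[3]], seed = 7, size = 64)
  expect_identical(img1, img2)
  expect_identical(dim(img1), c(64L, 64L, 3L))
  expect_true(is.integer(img1))
  expect_true(all(img1 >= 0 & img1 <= 255))
  # different seed or class changes the image
  expect_false(identical(img1, generate_leaf_image(cls[[3]], seed = 8, size = 64)))
  expect_false(identical(img1, generate_leaf_image(cls[[4]], seed = 7, size = 64)))
  big <- generate_leaf_image(cls[[1]], seed = 1, size = 224)
  expect_identical(dim(big), c(224L, 224L, 3L))
})

test_that("augmentation ops: involution, neutral element, noise statistics", {
  cls <- leaf_class_models(4)
  img <- generate_leaf_image(cls[[2]], seed = 3, size = 48)
  expect_identical(augment(img, list(augment_op("flip"), augment_op("flip"))), img)
  expect_identical(augment(img, list(augment_op("mirror"), augment_op("mirror"))), img)
  expect_identical(augment(img, list(augment_op("brightness", 1))), img)
  # four quarter-rotations restore the image
  r <- img
  for (i in 1:4) r <- augment(r, list(augment_op("rotate", 1)))
  expect_identical(r, img)
  expect_error(augment_op("swirl"), "unknown")
  expect_error(augment_op("noise", 100), "safe range")

  # noise changes pixels but keeps the mean within 5 gray levels
  changed <- numeric(100); dmean <- numeric(100)
  for (s in 1:100) {
    a <- augment(img, list(augment_op("noise", 5, seed = s)))
    changed[s] <- mean(a != img)
    dmean[s] <- abs(mean(a) - mean(img))
  }
  expect_true(all(changed >= 0.01))
  expect_true(all(dmean < 5))
})

test_that("splitting is stratified, deterministic, and near the global ratio", {
  cls <- leaf_class_models(1)
  man <- make_manifest(cls, per_class = 100, seed = 1)
  man <- split_dataset(man, c(4, 1), seed = 9)
  expect_equal(sum(man$split == "train"), 80)
  expect_equal(sum(man$split == "test"), 20)
  man2 <- split_dataset(make_manifest(cls, 100, seed = 1), c(4, 1), seed = 9)
  expect_identical(man$split, man2$split)

  cls25 <- leaf_class_models(25)
  set.seed(31)
  counts <- sample(20:120, 25, replace = TRUE)
  m25 <- split_dataset(make_manifest(cls25, counts, seed = 2), c(4, 1), seed = 3)
  for (id in unique(m25$class)) {
    n <- sum(m25$class == id)
    n_test <- sum(m25$class == id & m25$split == "test")
    expect_lte(abs(n_test - n / 5), 1)
  }
  tiny <- make_manifest(cls, per_class = 1, seed = 1)
  expect_warning(split_dataset(tiny, c(4, 1), 1), "fewer than 2")
})

test_that("augmentation balancing pads to targets without split leakage", {
  cls <- leaf_class_models(2)
  man <- make_manifest(cls, per_class = c(10, 4), seed = 5)
  man$split <- "train"
  out <- balance_by_augmentation(man, 12, seed = 6)
  expect_equal(as.integer(table(out$class)), c(12L, 12L))
  expect_equal(sum(out$provenance == "augmented"), 2 + 8)
  # targets below the current count subsample the class instead
  down <- balance_by_augmentation(man, 3, seed = 1)
  expect_equal(as.integer(table(down$class)), c(3L, 3L))
  expect_true(all(down$provenance == "original"))
  # and augmented records are dropped before originals
  mixed <- balance_by_augmentation(out, 11, seed = 2)
  expect_equal(as.integer(table(mixed$class)), c(11L, 11L))
  expect_equal(sum(mixed$class == 0 & mixed$provenance == "original"), 10)

  # leakage audit across random manifests: no augmented record may be
  # sourced from a record in the other split
  cls4 <- leaf_class_models(4)
  for (trial in 1:100) {
    m <- make_manifest(cls4, per_class = 6 + trial %% 5, seed = trial)
    m <- suppressWarnings(split_dataset(m, c(4, 1), seed = trial))
    m <- balance_by_augmentation(m, 15, split = "train", seed = trial)
    m <- balance_by_augmentation(m, 8, split = "test", seed = trial + 1)
    aug <- m[m$provenance == "augmented", ]
    src_split <- m$split[match(aug$source, m$path)]
    expect_true(all(src_split == aug$split))
    expect_true(all(m$class[match(aug$source, m$path)] == aug$class))
  }
})

test_that("published per-class targets reproduce the expanded totals", {
  counts <- plantvillage_counts()
  expect_equal(nrow(counts), 25)
  expect_equal(sum(counts$original), 30644)
  expect_equal(sum(counts$train), 37572)
  expect_equal(sum(counts$test), 10359)
})

test_that("manifest rendering round-trips through PNG files", {
  cls <- leaf_class_models(2)
  man <- make_manifest(cls, per_class = 2, seed = 3)
  man <- suppressWarnings(split_dataset(man, c(4, 1), seed = 3))
  man <- balance_by_augmentation(man, 3, split = "train", seed = 4)
  root <- tempfile("leafimgs")
  materialize_manifest(man, root, cls, size = 32)
  expect_true(all(file.exists(file.path(root, man$path))))
  img <- png::readPNG(file.path(root, man$path[1]))
  expect_identical(dim(img), c(32L, 32L, 3L))
  want <- generate_leaf_image(cls[[man$class[1] + 1]], man$seed[1], 32)
  expect_equal(round(img * 255), array(as.numeric(want), dim(want)),
               tolerance = 1e-8)
  unlink(root, recursive = TRUE)
})

test_that("a linear probe on raw pixel statistics beats chance on 25 classes", {
  skip_if_not_installed("nnet")
  cls <- leaf_class_models(25)
  n_per <- 8
  feats <- NULL; labs <- integer(0)
  for (cm in cls) for (i in seq_len(n_per)) {
    img <- generate_leaf_image(cm, seed = 1000 + cm$class_id * 100 + i, size = 32)
    ch_mean <- apply(img, 3, mean); ch_sd <- apply(img, 3, sd)
    feats <- rbind(feats, c(ch_mean, ch_sd))
    labs <- c(labs, cm$class_id)
  }
  train_idx <- seq_along(labs) %% n_per < 6
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(labs[train_idx]),
                                                 feats[train_idx, ]),
                        trace = FALSE, maxit = 300, MaxNWts = 5000)
  pred <- predict(fit, data.frame(feats[!train_idx, ]))
  acc <- mean(pred == factor(labs[!train_idx]))
  expect_gt(acc, 3 / 25)
})
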