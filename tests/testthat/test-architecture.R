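test_that("bottleneck-RepMLP block honours the table bookkeeping and skip path", {
  set.seed(51)
  # 64 x 14 x 14 input at r = 4: RepMLP runs at width 16, output 96 x 14 x 14
  blk <- nn_bottleneck_repmlp(64, 96, r = 4, resolution = 14)
  expect_equal(blk$layers$repmlp$channels, 16)
  expect_equal(blk$layers$repmlp$h, 7L)
  y <- bottleneck_repmlp_forward(rand_fm(1, 64, 14, 14), blk)
  expect_identical(dim(y), c(1L, 96L, 14L, 14L))

  # zero weights, matching channels, stride 1 -> pure skip path
  blkz <- zero_params_tree(nn_bottleneck_repmlp(8, 8, r = 2, resolution = 4))
  x <- rand_fm(2, 8, 4, 4)
  expect_equal(bottleneck_repmlp_forward(x, blkz), x)

  # stage-by-stage composition oracle
  blk3 <- randomize_bn_tree(nn_bottleneck_repmlp(8, 12, r = 2, resolution = 4,
                                                 activation = "hardswish"))
  x3 <- rand_fm(2, 8, 4, 4)
  l <- blk3$layers
  mid <- naive_conv2d(x3, l$reduce_conv$weight)
  mid <- naive_bn(mid, l$reduce_bn$gamma, l$reduce_bn$beta,
                  l$reduce_bn$stats$mean, l$reduce_bn$stats$var)
  mid <- hardswish(mid)
  mid <- repmlp_forward(mid, l$repmlp)
  out <- naive_conv2d(mid, l$expand_conv$weight)
  out <- naive_bn(out, l$expand_bn$gamma, l$expand_bn$beta,
                  l$expand_bn$stats$mean, l$expand_bn$stats$var)
  expect_lt(max(abs(bottleneck_repmlp_forward(x3, blk3) - out)), 1e-8)

  expect_error(nn_bottleneck_repmlp(10, 16, r = 4, resolution = 14),
               "divisible")
})

test_that("default model reproduces the printed stage-shape bookkeeping at 224", {
  m <- build_model(model_spec(seed = 3))
  tr <- model_shape_trace(m, rand_fm(1, 3, 224, 224))
  expect_equal(tr$stem, c(1, 32, 112, 112))
  expect_equal(tr$B1_1, c(1, 16, 112, 112))
  expect_equal(tr$B2_2, c(1, 24, 56, 56))
  expect_equal(tr$B3_3, c(1, 32, 28, 28))
  expect_equal(tr$B4_4, c(1, 64, 14, 14))
  expect_equal(tr$B5_3, c(1, 96, 14, 14))
  expect_equal(tr$B6_1, c(1, 160, 7, 7))
  expect_equal(tr$B7_1, c(1, 320, 7, 7))
  expect_equal(tr$head_conv, c(1, 1280, 7, 7))
  expect_equal(tr$classifier, c(1, 25))
})

test_that("variant construction follows the ablation grids", {
  v1 <- make_variant(c("B4", "B5", "B6", "B7"), r = 4)
  expect_setequal(v1$repmlp_stages, c("B4", "B5", "B6", "B7"))
  expect_equal(v1$num_classes, 10)
  v2 <- make_variant(c("B5", "B6", "B7"), r = 8)
  expect_equal(v2$r, 8)
  expect_error(make_variant("B5", r = 3), "r must be")
  expect_error(make_variant("B9"), "subset")
  # empty stage set reduces to plain MobileNetV2
  v0 <- make_variant(character(0), r = 4, num_classes = 10)
  m0 <- build_model(v0)
  expect_false(any(vapply(m0$layers, inherits, TRUE,
                          what = "nn_bottleneck_repmlp")))
  mref <- build_model(mobilenet_v2_spec(10, input_size = 32))
  expect_equal(count_params(m0), count_params(mref))
  expect_equal(names(m0$layers), names(mref$layers))
})

test_that("10-logit variant and hand-counted MobileNetV2 total agree", {
  m10 <- build_model(model_spec(num_classes = 10, input_size = 64, seed = 2))
  y <- model_forward(m10, rand_fm(2, 3, 64, 64))
  expect_identical(dim(y), c(2L, 10L))

  # independent closed-form count of the standard MobileNetV2 backbone
  ir <- function(cin, cout, t) {
    hid <- cin * t
    (if (t > 1) cin * hid + 2 * hid else 0) + 9 * hid + 2 * hid +
      hid * cout + 2 * cout
  }
  total <- (3 * 32 * 9 + 64) + ir(32, 16, 1) +
    ir(16, 24, 6) + ir(24, 24, 6) +
    ir(24, 32, 6) + 2 * ir(32, 32, 6) +
    ir(32, 64, 6) + 3 * ir(64, 64, 6) +
    ir(64, 96, 6) + 2 * ir(96, 96, 6) +
    ir(96, 160, 6) + 2 * ir(160, 160, 6) +
    ir(160, 320, 6) +
    (320 * 1280 + 2 * 1280) + (1280 * 25 + 25)
  expect_equal(count_params(build_model(mobilenet_v2_spec(25))), total)
})

test_that("parameter totals are monotone across the ablation grids", {
  p_of <- function(stages, r) count_params(build_model(make_variant(stages, r)))
  b5to7 <- c("B5", "B6", "B7")
  # channel-reduction grid: r = 8 < r = 4 < r = 2
  expect_lt(p_of(b5to7, 8), p_of(b5to7, 4))
  expect_lt(p_of(b5to7, 4), p_of(b5to7, 2))
  # stage grid: more replaced stages -> fewer parameters, all below baseline
  p1 <- p_of(c("B4", b5to7), 4)
  p2 <- p_of(b5to7, 4)
  p3 <- p_of(c("B6", "B7"), 4)
  p4 <- p_of("B7", 4)
  p0 <- count_params(build_model(mobilenet_v2_spec(10, input_size = 32)))
  expect_true(p1 < p2 && p2 < p3 && p3 < p4 && p4 < p0)
})

test_that("model-level re-parameterization preserves logits and counts", {
  set.seed(52)
  m <- randomize_bn_tree(build_model(model_spec(num_classes = 6, input_size = 64,
                                                seed = 4)))
  dep <- reparameterize(m)
  for (i in 1:5) {
    x <- rand_fm(2, 3, 64, 64)
    expect_lt(max(abs(model_forward(m, x) - model_forward(dep, x))), 1e-4)
  }
  expect_equal(params_m(dep), params_m(m))
})
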