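test_that("cost ratio follows 1/N + 1/K^2 and rejects bad input", {
  expect_equal(cost_ratio(1, 1), 2.0)
  expect_equal(cost_ratio(3, 9), 1 / 9 + 1 / 9)
  expect_equal(cost_ratio(3, Inf), 1 / 9)
  expect_error(cost_ratio(0, 4))
  expect_error(cost_ratio(3, -1))
})

test_that("depthwise-separable pass matches zero, identity and dense-composition oracles", {
  set.seed(101)
  dw <- nn_conv2d(4, 4, 3, padding = 1, groups = 4, init = "zero")
  pw <- nn_conv2d(4, 4, 1, init = "zero")
  x <- rand_fm(1, 4, 8, 8)
  expect_equal(depthwise_separable_forward(x, dw, pw), array(0, dim(x)))

  # identity composition: center-1 depthwise kernel, identity pointwise
  dw$weight[, 1, 2, 2] <- 1
  for (c in 1:4) pw$weight[c, c, 1, 1] <- 1
  expect_equal(depthwise_separable_forward(x, dw, pw), x, tolerance = 1e-12)

  # random dw/pw equals a dense standard conv whose kernel is the
  # composition W_dense[o, i, ., .] = pw[o, i] * dw_kernel[i]
  dw <- nn_conv2d(4, 4, 3, padding = 1, groups = 4)
  pw <- nn_conv2d(4, 4, 1)
  wd <- array(0, c(4, 4, 3, 3))
  for (o in 1:4) for (i in 1:4) wd[o, i, , ] <- pw$weight[o, i, 1, 1] * dw$weight[i, 1, , ]
  got <- depthwise_separable_forward(x, dw, pw)
  want <- naive_conv2d(x, wd, pad = 1)
  expect_lt(max(abs(got - want)), 1e-10)

  expect_error(depthwise_separable_forward(rand_fm(1, 3, 8, 8), dw, pw),
               "channel")
})

test_that("grouped conv agrees with the direct-summation oracle across configs", {
  set.seed(7)
  cfgs <- list(list(k = 3, s = 1, p = 1, g = 1), list(k = 3, s = 2, p = 1, g = 2),
               list(k = 1, s = 1, p = 0, g = 1), list(k = 5, s = 1, p = 2, g = 4),
               list(k = 3, s = 1, p = 0, g = 8))
  for (cf in cfgs) {
    x <- rand_fm(2, 8, 7, 7)
    w <- array(rnorm(8 * (8 / cf$g) * cf$k^2), c(8, 8 / cf$g, cf$k, cf$k))
    b <- rnorm(8)
    got <- conv2d_forward(x, w, b, cf$s, cf$p, cf$g)
    want <- naive_conv2d(x, w, b, cf$s, cf$p, cf$g)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("activations match their closed forms at the documented points", {
  expect_equal(hardswish(0), 0)
  expect_equal(hardswish(-3), 0)
  expect_equal(hardswish(3), 3)
  expect_equal(hardswish(100), 100)
  expect_equal(relu6(7), 6)
  expect_equal(relu6(-1), 0)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(hardswish(x), x * pmin(pmax(x + 3, 0), 6) / 6)
  expect_equal(relu6(x), pmin(pmax(x, 0), 6))
})

test_that("ECA kernel size map gives the documented sizes and is monotone", {
  expect_equal(eca_kernel_size(64, 2, 1), 3L)
  expect_equal(eca_kernel_size(256, 2, 1), 5L)
  ks <- vapply(2^(1:11), eca_kernel_size, integer(1))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(diff(ks) >= 0))
  # monotone over arbitrary channel counts too
  cs <- sort(sample(1:2048, 50))
  expect_true(all(diff(vapply(cs, eca_kernel_size, integer(1))) >= 0))
})

test_that("ECA gating: sigmoid(0) halves, magnitude shrinks, oracle agrees", {
  set.seed(11)
  x <- rand_fm(2, 8, 4, 4)
  expect_equal(eca_forward(x, numeric(3)), x / 2, tolerance = 1e-12)
  w <- rnorm(3)
  y <- eca_forward(x, w)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_true(all(sign(y) == sign(x) | x == 0))
  expect_identical(dim(y), dim(x))
  expect_lt(max(abs(y - naive_eca(x, w))), 1e-10)
  expect_error(nn_eca(2, k = 5), "longer")
})

test_that("inverted residual: skip identity, strided shapes, composition oracle", {
  # zero weights + identity BN + matching channels => identity map
  blk <- zero_params_tree(nn_inverted_residual(6, 6, expand_t = 4, stride = 1))
  blk$layers$proj_bn$gamma <- rep(1, 6)  # zero_params zeroed gamma; restore scale
  blk$layers$dw_bn$gamma <- rep(1, 24)
  blk$layers$expand_bn$gamma <- rep(1, 24)
  x <- rand_fm(2, 6, 6, 6)
  expect_equal(inverted_residual_forward(x, blk), x, tolerance = 1e-12)

  # table bookkeeping: 16 x 112 x 112, t = 6, out 24, s = 2 -> 24 x 56 x 56
  blk2 <- nn_inverted_residual(16, 24, expand_t = 6, stride = 2)
  y <- inverted_residual_forward(rand_fm(1, 16, 112, 112), blk2)
  expect_identical(dim(y), c(1L, 24L, 56L, 56L))

  # layer-by-layer composition oracle on a random instance
  set.seed(21)
  blk3 <- randomize_bn_tree(nn_inverted_residual(4, 5, expand_t = 3, stride = 1))
  x3 <- rand_fm(2, 4, 6, 6)
  l <- blk3$layers
  mid <- naive_conv2d(x3, l$expand_conv$weight)
  mid <- naive_bn(mid, l$expand_bn$gamma, l$expand_bn$beta,
                  l$expand_bn$stats$mean, l$expand_bn$stats$var)
  mid <- relu6(mid)
  mid <- naive_conv2d(mid, l$dw_conv$weight, stride = 1, pad = 1, groups = 12)
  mid <- naive_bn(mid, l$dw_bn$gamma, l$dw_bn$beta,
                  l$dw_bn$stats$mean, l$dw_bn$stats$var)
  mid <- relu6(mid)
  out <- naive_conv2d(mid, l$proj_conv$weight)
  out <- naive_bn(out, l$proj_bn$gamma, l$proj_bn$beta,
                  l$proj_bn$stats$mean, l$proj_bn$stats$var)
  expect_lt(max(abs(inverted_residual_forward(x3, blk3) - out)), 1e-8)
})

test_that("depthwise-separable FLOP count reproduces the analytic ratio", {
  set.seed(31)
  for (i in 1:10) {
    K <- sample(c(3, 5), 1)
    C <- sample(c(4, 8, 16), 1)
    N <- sample(c(8, 16, 32), 1)
    H <- sample(c(8, 14), 1)
    dw <- nn_conv2d(C, C, K, padding = (K - 1) / 2, groups = C)
    pw <- nn_conv2d(C, N, 1)
    std <- nn_conv2d(C, N, K, padding = (K - 1) / 2)
    f_dw <- layer_profile(dw, c(C, H, H))$rows$flops
    f_pw <- layer_profile(pw, c(C, H, H))$rows$flops
    f_std <- layer_profile(std, c(C, H, H))$rows$flops
    expect_equal((f_dw + f_pw) / f_std, cost_ratio(K, N), tolerance = 1e-12)
  }
})
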