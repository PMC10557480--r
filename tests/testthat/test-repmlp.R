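test_that("partition split/merge is a bit-exact inverse pair with documented order", {
  x <- array(1:16, c(1, 1, 4, 4))
  p <- partition_split(x, 2, 2)
  expect_identical(dim(p), c(4L, 1L, 2L, 2L))
  # first partition is the top-left tile; partition index runs column-of-
  # patches fastest (row-major over the patch grid)
  expect_equal(p[1, 1, , ], x[1, 1, 1:2, 1:2])
  expect_equal(p[2, 1, , ], x[1, 1, 1:2, 3:4])
  expect_equal(p[3, 1, , ], x[1, 1, 3:4, 1:2])
  expect_identical(partition_merge(p, 1, 4, 4), x)

  y <- rand_fm(1, 24, 14, 14)
  py <- partition_split(y, 7, 7)
  expect_identical(dim(py)[1], 4L)

  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:3, 1); c <- sample(1:6, 1)
    h <- sample(c(1, 2, 7), 1); w <- sample(c(1, 2, 7), 1)
    H <- h * sample(1:3, 1); W <- w * sample(1:3, 1)
    z <- rand_fm(n, c, H, W)
    expect_identical(partition_merge(partition_split(z, h, w), n, H, W), z)
  }
  expect_error(partition_split(rand_fm(1, 2, 5, 5), 2, 2), "divisible")
})

test_that("global perceptron adds the pooled-FC correction", {
  set.seed(5)
  pt <- rand_fm(6, 8, 3, 3)
  fc1 <- nn_linear(8, 2, init = "zero")
  fc2 <- nn_linear(2, 8, init = "zero")
  # both FC weights (and biases) zero -> additive branch contributes nothing
  expect_equal(global_perceptron(pt, fc1, fc2), pt)
  # constant-valued partition, hand-computable weights -> uniform shift
  ptc <- array(2, c(1, 2, 2, 2))
  fc1 <- nn_linear(2, 1, init = "zero"); fc1$weight[] <- 1; fc1$bias <- 0.5
  fc2 <- nn_linear(1, 2, init = "zero"); fc2$weight[] <- c(1, -1); fc2$bias <- c(0, 1)
  # gap = (2,2); z1 = 2+2+0.5 = 4.5; relu -> 4.5; z2 = (4.5, -4.5+1) = (4.5, -3.5)
  out <- global_perceptron(ptc, fc1, fc2)
  expect_equal(out[1, 1, , ], matrix(2 + 4.5, 2, 2))
  expect_equal(out[1, 2, , ], matrix(2 - 3.5, 2, 2))
  # shape preserved on random input
  fc1 <- nn_linear(8, 2); fc2 <- nn_linear(2, 8)
  expect_identical(dim(global_perceptron(pt, fc1, fc2)), dim(pt))
})

test_that("partition perceptron: identity, zero-weight shift, dense matmul oracle", {
  set.seed(6)
  pt <- rand_fm(3, 4, 2, 2)
  # identity weights, identity BN -> passthrough
  fc <- nn_grouped_fc(4, 4, 2, 2, groups = 1, init = "zero")
  fc$weight[, , 1] <- diag(16)
  expect_equal(partition_perceptron(pt, fc, identity_bn(4)), pt, tolerance = 1e-9)
  # zero weights -> BN shift beta everywhere
  fcz <- nn_grouped_fc(4, 4, 2, 2, groups = 1, init = "zero")
  bn <- identity_bn(4); bn$beta <- c(1, -2, 3, 0.5)
  out <- partition_perceptron(pt, fcz, bn)
  for (c in 1:4) expect_true(all(abs(out[, c, , ] - bn$beta[c]) < 1e-12))
  # grouped random instance vs explicit per-group matmul
  fcr <- nn_grouped_fc(4, 6, 2, 2, groups = 2)
  got <- partition_perceptron(pt, fcr, NULL)
  for (p in 1:3) for (g in 1:2) {
    xv <- as.numeric(pt[p, (g - 1) * 2 + 1:2, , ])
    yv <- matrix(fcr$weight[, , g], 12, 8) %*% xv
    expect_equal(as.numeric(got[p, (g - 1) * 3 + 1:3, , ]), as.numeric(yv),
                 tolerance = 1e-12)
  }
  expect_error(nn_grouped_fc(4, 5, 2, 2, groups = 2))
})

test_that("local perceptron sums conv+BN branches and matches per-branch oracle", {
  set.seed(8)
  pt <- rand_fm(2, 4, 7, 7)
  # zero branches contribute nothing
  bz <- list(list(conv = nn_conv2d(4, 4, 3, padding = 1, groups = 4, init = "zero"),
                  bn = identity_bn(4)))
  expect_equal(local_perceptron(pt, bz), array(0, dim(pt)))
  # single 1x1 branch with scalar weight 2 doubles each channel
  b2 <- nn_conv2d(4, 4, 1, groups = 4, init = "zero"); b2$weight[] <- 2
  expect_equal(local_perceptron(pt, list(list(conv = b2, bn = identity_bn(4)))),
               2 * pt, tolerance = 1e-12)
  # K in {1,3,5} branches vs direct convolution oracle
  branches <- lapply(c(1, 3, 5), function(K) {
    list(conv = nn_conv2d(4, 4, K, padding = (K - 1) / 2, groups = 4),
         bn = randomize_bn_tree(identity_bn(4)))
  })
  want <- Reduce(`+`, lapply(branches, function(b) {
    naive_bn(naive_conv2d(pt, b$conv$weight, pad = (dim(b$conv$weight)[3] - 1) / 2,
                          groups = 4),
             b$bn$gamma, b$bn$beta, b$bn$stats$mean, b$bn$stats$var,
             eps = b$bn$eps)
  }))
  expect_lt(max(abs(local_perceptron(pt, branches) - want)), 1e-10)
})

test_that("repmlp forward: zero weights, shape contract, monolithic oracle", {
  set.seed(9)
  blk <- zero_params_tree(nn_repmlp(4, 2, 2))
  x <- rand_fm(2, 4, 4, 4)
  expect_equal(repmlp_forward(x, blk), array(0, dim(x)))

  blk16 <- nn_repmlp(16, 7, 7)
  y <- repmlp_forward(rand_fm(1, 16, 14, 14), blk16)
  expect_identical(dim(y), c(1L, 16L, 14L, 14L))

  # monolithic oracle: evaluate the three perceptrons by explicit summation
  blk2 <- randomize_bn_tree(nn_repmlp(8, 2, 2, groups = 2, kernels = 1))
  x2 <- rand_fm(2, 8, 4, 4)
  pt <- partition_split(x2, 2, 2)
  ptg <- global_perceptron(pt, blk2$layers$fc1, blk2$layers$fc2)
  part <- partition_perceptron(ptg, blk2$layers$part_fc, blk2$layers$part_bn)
  loc <- local_perceptron(ptg, list(list(conv = blk2$layers$local1_conv,
                                         bn = blk2$layers$local1_bn)))
  want <- partition_merge(part + loc, 2, 4, 4)
  expect_lt(max(abs(repmlp_forward(x2, blk2) - want)), 1e-10)
})

test_that("repmlp forward is linear in x once nonlinearities are bypassed", {
  # zero the global FC path (its ReLU is the only nonlinearity); BN at
  # inference is affine, so f(a x1 + b x2) + f(0) == a f(x1) + b f(x2) + ...
  # use gamma-only BN (beta = 0, mean = 0) to make the path strictly linear
  set.seed(10)
  blk <- nn_repmlp(4, 2, 2)
  blk$layers$fc1 <- nn_linear(4, 1, init = "zero")
  blk$layers$fc2 <- nn_linear(1, 4, init = "zero")
  for (nm in c("part_bn", "local1_bn")) {
    blk$layers[[nm]]$beta <- numeric(4)
    blk$layers[[nm]]$stats$mean <- numeric(4)
  }
  x1 <- rand_fm(1, 4, 4, 4); x2 <- rand_fm(1, 4, 4, 4)
  f <- function(x) repmlp_forward(x, blk)
  expect_lt(max(abs(f(2 * x1 - 3 * x2) - (2 * f(x1) - 3 * f(x2)))), 1e-8)
})

test_that("conv/BN fusion reproduces the closed form and the forward map", {
  set.seed(12)
  w <- array(rnorm(4 * 4 * 9), c(4, 4, 3, 3))
  b <- rnorm(4)
  ident <- bn_params(rep(1, 4), numeric(4), numeric(4), rep(1, 4), eps = 1e-12)
  f <- fuse_bn_into_conv(w, b, ident)
  expect_equal(f$weight, w, tolerance = 1e-9)
  expect_equal(f$bias, b, tolerance = 1e-9)

  dbl <- bn_params(rep(2, 4), numeric(4), numeric(4), rep(1, 4), eps = 1e-12)
  expect_equal(fuse_bn_into_conv(w, b, dbl)$weight, 2 * w, tolerance = 1e-9)

  bn <- bn_params(runif(4, 0.5, 2), rnorm(4), rnorm(4), runif(4, 0.5, 2))
  fr <- fuse_bn_into_conv(w, b, bn)
  x <- rand_fm(2, 4, 5, 5)
  pre <- naive_conv2d(x, w, b, pad = 1)
  want <- naive_bn(pre, bn$gamma, bn$beta, bn$mean, bn$var)
  got <- naive_conv2d(x, fr$weight, fr$bias, pad = 1)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("conv_to_fc probe matrix reproduces the convolution exactly", {
  # 1x1 conv, weight 2, C = 1 -> 2 * identity
  w1 <- array(2, c(1, 1, 1, 1))
  expect_equal(conv_to_fc(w1, 2, 2, 1), 2 * diag(4))
  # 3x3 all-ones kernel, p = 1, 2x2 partition: every output sees all inputs
  w3 <- array(1, c(1, 1, 3, 3))
  expect_equal(conv_to_fc(w3, 2, 2, 1), matrix(1, 4, 4))
  # random kernels: M %*% vec(x) == vec(conv(x)) on 50 random partitions
  set.seed(13)
  w <- array(rnorm(3 * 3 * 9), c(3, 3, 3, 3))
  M <- conv_to_fc(w, 4, 4, 3)
  for (i in 1:50) {
    x <- rand_fm(1, 3, 4, 4)
    got <- M %*% as.numeric(aperm(x, c(2, 3, 4, 1)))
    want <- as.numeric(aperm(naive_conv2d(x, w, pad = 1), c(2, 3, 4, 1)))
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("re-parameterization: zero-local case and random-spec equivalence", {
  set.seed(14)
  # zero local branches + identity BN: deployed FC equals the training FC
  blk <- nn_repmlp(4, 2, 2, groups = 1)
  blk$layers$part_bn$eps <- 1e-12
  for (K in blk$kernels) {
    ck <- sprintf("local%d_conv", K)
    blk$layers[[ck]]$weight[] <- 0
    blk$layers[[sprintf("local%d_bn", K)]]$eps <- 1e-12
  }
  dep <- reparameterize(blk)
  expect_equal(dep$layers$part_fc$weight, blk$layers$part_fc$weight,
               tolerance = 1e-8)
  expect_true(dep$deployed)
  expect_null(dep$layers$local1_conv)
  expect_error(reparameterize(dep), "already")

  # random specs drawn from the calibration-relevant grid
  for (i in 1:30) {
    h <- sample(c(2, 7), 1)
    C <- sample(c(4, 8, 16), 1)
    g <- sample(c(1, 2, 4), 1)
    ks <- sort(sample(c(1, 3, 5)[c(1, 3, 5) <= h],
                      sample(sum(c(1, 3, 5) <= h), 1)))
    blk <- randomize_bn_tree(nn_repmlp(C, h, h, groups = g, kernels = ks))
    x <- rand_fm(2, C, 2 * h, h)
    y1 <- repmlp_forward(x, blk)
    dep <- reparameterize(blk)
    y2 <- repmlp_forward(x, dep)
    expect_lt(max(abs(y1 - y2)), 1e-5)
  }
})

test_that("weight archives round-trip a model including BN statistics", {
  set.seed(15)
  m <- randomize_bn_tree(build_model(model_spec(num_classes = 3, input_size = 32,
                                                seed = 2)))
  x <- rand_fm(2, 3, 32, 32)
  y1 <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_weights(m, path)
  m2 <- build_model(model_spec(num_classes = 3, input_size = 32, seed = 99))
  m2 <- load_weights(m2, path)
  expect_equal(model_forward(m2, x), y1, tolerance = 1e-12)
  keys <- names(readRDS(path))
  expect_true(all(grepl("^[A-Za-z0-9_]+(\\.[A-Za-z0-9_]+)+$", keys)))
  unlink(path)
})
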