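conv_apply <- function(kernel, x, bias = NULL) {
  op_conv2d(x, kernel$weights, bias, stride = kernel$stride,
            pad = kernel$padding, groups = kernel$groups)
}

bn_apply <- function(bn, x) {
  st <- new.env()
  st$running_mean <- bn$running_mean
  st$running_var <- bn$running_var
  op_batchnorm(x, bn$gamma, bn$beta, st, training = FALSE, eps = bn$eps)
}

random_bn <- function(c) {
  bn_params(runif(c, 0.5, 2), rnorm(c), rnorm(c, sd = 0.5),
            runif(c, 0.3, 2), eps = 1e-3)
}

test_that("batch norm folds into the preceding convolution", {
  set.seed(1)
  k <- conv_kernel(array(rnorm(4 * 3 * 9), c(4, 3, 3, 3)))
  ident <- bn_params(rep(1, 4), rep(0, 4), rep(0, 4), rep(1, 4), eps = 0)
  f <- fuse_conv_bn(k, ident)
  expect_equal(f$kernel$weights, k$weights)
  expect_equal(f$bias, rep(0, 4))

  affine <- bn_params(rep(2, 4), rep(3, 4), rep(0, 4), rep(1, 4), eps = 0)
  f2 <- fuse_conv_bn(k, affine)
  expect_equal(f2$kernel$weights, 2 * k$weights)
  expect_equal(f2$bias, rep(3, 4))

  expect_error(bn_params(1, 0, 0, -0.1), "negative running variance")

  bn <- random_bn(4)
  fz <- fuse_conv_bn(k, bn)
  x <- array(rnorm(3 * 8 * 8 * 1), c(3, 8, 8, 1))
  direct <- bn_apply(bn, conv_apply(k, x))
  fused <- conv_apply(fz$kernel, x, fz$bias)
  expect_lt(max(abs(direct - fused)), 1e-5)
})

test_that("a 1x1 kernel embeds into the centre tap of a 3x3 kernel", {
  set.seed(2)
  k1 <- conv_kernel(array(rnorm(4 * 3), c(4, 3, 1, 1)), padding = 0L)
  k3 <- embed_1x1_in_3x3(k1)
  expect_equal(dim(k3$weights), c(4L, 3L, 3L, 3L))
  expect_equal(k3$weights[, , 2, 2], k1$weights[, , 1, 1])
  expect_equal(sum(k3$weights != 0), sum(k1$weights != 0))

  x <- array(rnorm(3 * 6 * 6 * 1), c(3, 6, 6, 1))
  expect_lt(max(abs(conv_apply(k1, x) - conv_apply(k3, x))), 1e-6)

  z <- embed_1x1_in_3x3(conv_kernel(array(0, c(2, 2, 1, 1)), padding = 0L))
  expect_true(all(z$weights == 0))
  expect_error(embed_1x1_in_3x3(conv_kernel(array(0, c(2, 2, 3, 3)))),
               "kernel size must be 1")
})

test_that("the Dirac kernel implements the identity map", {
  id2 <- identity_as_3x3(2)
  expect_equal(dim(id2$weights), c(2L, 2L, 3L, 3L))
  expect_equal(id2$weights[1, 1, 2, 2], 1)
  expect_equal(id2$weights[2, 2, 2, 2], 1)
  expect_equal(sum(id2$weights), 2)

  set.seed(3)
  x <- array(rnorm(4 * 5 * 5 * 2), c(4, 5, 5, 2))
  expect_lt(max(abs(conv_apply(identity_as_3x3(4), x) - x)), 1e-12)

  g4 <- identity_as_3x3(4, groups = 4)
  expect_equal(dim(g4$weights), c(4L, 1L, 3L, 3L))
  expect_lt(max(abs(conv_apply(g4, x) - x)), 1e-12)
  expect_error(identity_as_3x3(5, groups = 2), "not divisible")
})

frozen_unit <- function(cin, cout, seed = 1) {
  set.seed(seed)
  u <- repvgg_unit(cin, cout)
  for (st in list(u$bn3, u$bn1, if (u$has_identity) u$bnid)) {
    if (is.null(st)) next
    st$running_mean <- rnorm(cout, sd = 0.3)
    st$running_var <- runif(cout, 0.4, 1.6)
  }
  for (p in list(u$g3, u$g1, if (u$has_identity) u$gid)) {
    if (!is.null(p)) p$value <- runif(cout, 0.6, 1.4)
  }
  for (p in list(u$b3, u$b1, if (u$has_identity) u$bid)) {
    if (!is.null(p)) p$value <- rnorm(cout, sd = 0.3)
  }
  u
}

test_that("unit fusion is forward-equivalent to the branch sum", {
  u <- frozen_unit(4, 4, seed = 4)
  before <- count_parameters(u)
  xs <- lapply(1:20, function(i) array(rnorm(4 * 7 * 7 * 1), c(4, 7, 7, 1)))
  y0 <- lapply(xs, function(x) u$forward(x, training = FALSE))
  reparameterize_unit(u)
  expect_true(u$fused)
  y1 <- lapply(xs, function(x) u$forward(x, training = FALSE))
  dev <- max(mapply(function(a, b) max(abs(a - b)), y0, y1))
  expect_lt(dev, 1e-5)
  # fused parameter count: cout * cin * 9 + cout, strictly below training
  expect_equal(count_parameters(u), 4 * 4 * 9 + 4)
  expect_lt(count_parameters(u), before)
  expect_error(reparameterize_unit(u), "already fused")
})

test_that("a unit with a silenced pointwise branch equals the fused dense branch", {
  u <- frozen_unit(3, 5, seed = 5)   # cin != cout: no identity branch
  expect_false(u$has_identity)
  u$w1$value[] <- 0
  u$b1$value[] <- 0
  u$bn1$running_mean[] <- 0
  ref <- fuse_conv_bn(conv_kernel(u$w3$value),
                      bn_params(u$g3$value, u$b3$value,
                                u$bn3$running_mean, u$bn3$running_var))
  reparameterize_unit(u)
  expect_equal(u$wf$value, ref$kernel$weights, tolerance = 1e-12)
  expect_equal(u$bf$value, ref$bias, tolerance = 1e-12)
})

test_that("network-level fusion preserves outputs and rejects misuse", {
  set.seed(6)
  model <- build_model(toy_model_config())
  randomize_bn_stats(model)
  x <- array(rnorm(3 * 64 * 64 * 1), c(3, 64, 64, 1))
  y0 <- forward_model(model, x)
  set_training(model, TRUE)
  expect_error(reparameterize_network(model), "inference mode")
  set_training(model, FALSE)
  reparameterize_network(model)
  y1 <- forward_model(model, x)
  dev <- max(mapply(function(a, b) {
    max(abs(a$box - b$box), abs(a$cls - b$cls), abs(a$kpt - b$kpt))
  }, y0, y1))
  expect_lt(dev, 1e-4)
  expect_error(reparameterize_network(model), "already reparameterized")

  # a model without reparameterizable units passes through unchanged
  base <- build_model(toy_baseline_config())
  p0 <- count_parameters(base)
  reparameterize_network(base)
  expect_identical(count_parameters(base), p0)
})

test_that("fusion never changes output shapes or strides", {
  set.seed(7)
  u <- frozen_unit(6, 6, seed = 7)
  x <- array(rnorm(6 * 8 * 8 * 1), c(6, 8, 8, 1))
  d0 <- dim(u$forward(x, FALSE))
  reparameterize_unit(u)
  expect_identical(dim(u$forward(x, FALSE)), d0)
})
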