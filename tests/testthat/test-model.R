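# Architecture construction, parameter accounting, forward pass.

test_that("the default model fits in the 304 KB parameter budget", {
  net <- build_net(net_config(), seed = 1)
  expect_lte(parameter_bytes(net), 304 * 1024)
})

test_that("config validation catches bad architectures", {
  expect_error(net_config(n_classes = 1), "n_classes")
  expect_error(net_config(input_length = 10),
               "minimum is 19")            # names the minimum length
  expect_error(net_config(channel_growth = 1.0))
})

test_that("default channel widths follow x1.5 growth with round-half-up", {
  expect_identical(net_config()$widths, c(20L, 30L, 45L, 68L))
})

test_that("a toy configuration matches the hand-enumerated parameter count", {
  cfg <- net_config(stem_channels = 2, stem_kernel = 3, stem_stride = 1,
                    n_layers = 1, blocks_per_layer = 1, channel_growth = 1.5,
                    block_kernel = 3, n_classes = 2, input_length = 20)
  net <- build_net(cfg, seed = 1)
  # stem: conv 2x1x3 = 6, bn 2+2 (+run 2+2)
  # block (cin 2, mid 1, out 2, stride 2, projection):
  #   c1 1x2 = 2, bn 1+1 (+2); c2 1x1x3 = 3, bn 1+1 (+2)
  #   c3 2x1 = 2, bn 2+2 (+4); shortcut 2x2 = 4, bn 2+2 (+4)
  # head: fc 2x2 + 2 = 6
  params <- 6 + 4 + (2 + 2 + 3 + 2 + 2 + 4 + 4 + 4) + 6
  buffers <- 4 + (2 + 2 + 4 + 4)
  expect_equal(sum(lengths(net$params)), params)
  expect_equal(sum(lengths(net$buffers)), buffers)
  expect_equal(parameter_bytes(net), 4L * (params + buffers))
})

test_that("parameter storage grows with stem width", {
  b1 <- parameter_bytes(build_net(net_config(stem_channels = 20), 1))
  b2 <- parameter_bytes(build_net(net_config(stem_channels = 40), 1))
  expect_gt(b2, b1)
})

test_that("building is bit-deterministic given config and seed", {
  n1 <- build_net(net_config(), seed = 7)
  n2 <- build_net(net_config(), seed = 7)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$buffers, n2$buffers)
  n3 <- build_net(net_config(), seed = 8)
  expect_false(identical(n1$params, n3$params))
})

test_that("forward output rows lie on the probability simplex", {
  cfg <- tiny_config(300)
  net <- build_net(cfg, seed = 2)
  set.seed(21)
  for (i in 1:10) {
    x <- matrix(rnorm(100 * 300, sd = runif(1, 0.1, 10)), 100, 300)
    p <- net_forward(net, x)
    expect_equal(dim(p), c(100L, 2L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), rep(1, 100), tolerance = 1e-6)
  }
})

test_that("duplicated input rows give identical output rows", {
  net <- build_net(tiny_config(300), seed = 3)
  set.seed(4)
  x <- matrix(rnorm(300), 1, 300)
  p <- net_forward(net, rbind(x, x, x))
  expect_equal(p[1, ], p[2, ])
  expect_equal(p[1, ], p[3, ])
})

test_that("zeroing the fully connected layer yields uniform probabilities", {
  for (k in c(2L, 4L)) {
    net <- build_net(tiny_config(300, n_classes = k), seed = 5)
    net$params$fc.W[] <- 0
    net$params$fc.b[] <- 0
    p <- net_forward(net, matrix(rnorm(3 * 300), 3, 300))
    expect_equal(p, matrix(1 / k, 3, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("trunk lengths follow the stride arithmetic for any input length", {
  # default: stem (3000-19)/3+1 = 994, then eight stride-2 blocks
  cfg <- net_config()
  expect_identical(poreclass:::.trunk_lengths(cfg),
                   c(994L, 497L, 249L, 125L, 63L, 32L, 16L, 8L, 4L))
  set.seed(6)
  for (L in sample(30:2000, 5)) {
    cfg <- tiny_config(L)
    net <- build_net(cfg, seed = 1)
    lens <- poreclass:::.trunk_lengths(cfg)
    expect_equal(net$arch$trunk_len, lens[length(lens)])
    p <- net_forward(net, matrix(rnorm(2 * L), 2, L))  # forward must agree
    expect_equal(dim(p), c(2L, 2L))
  }
})

test_that("wrong window lengths are a shape error", {
  net <- build_net(tiny_config(300), seed = 1)
  expect_error(net_forward(net, matrix(0, 2, 299)), "expects 300")
})

test_that("checkpoints restore an identical model", {
  net <- build_net(tiny_config(300), seed = 9)
  set.seed(10); x <- matrix(rnorm(4 * 300), 4, 300)
  path <- withr::local_tempfile(fileext = ".rds")
  save_net(net, path)
  net2 <- load_net(path)
  expect_identical(net2$params, net$params)
  expect_equal(net_forward(net2, x), net_forward(net, x))
})

test_that("training-mode batch statistics update the running buffers", {
  net <- build_net(tiny_config(300), seed = 11)
  mb <- poreclass:::.windows_to_batch(matrix(rnorm(8 * 300), 8, 300), 300)
  fwd <- poreclass:::.net_apply(net, mb$X, mb$B, train = TRUE, with_cache = FALSE)
  expect_false(identical(fwd$buffers, net$buffers))
  # evaluation mode leaves them untouched
  fwd2 <- poreclass:::.net_apply(net, mb$X, mb$B, train = FALSE, with_cache = FALSE)
  expect_identical(fwd2$buffers, net$buffers)
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- net_config(stem_channels = 3, stem_kernel = 5, stem_stride = 2,
                    n_layers = 2, blocks_per_layer = 1, channel_growth = 1.5,
                    input_length = 40)
  net <- build_net(cfg, seed = 42)
  set.seed(7)
  x <- matrix(rnorm(3 * 40), 3, 40)
  y <- c(1L, 2L, 1L)
  mb <- poreclass:::.windows_to_batch(x, 40)
  fwd <- poreclass:::.net_apply(net, mb$X, mb$B, train = TRUE, with_cache = TRUE)
  bwd <- poreclass:::.net_backward(net, fwd$caches,
                                   poreclass:::.ce_grad(fwd$probs, y), mb$B)
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    f <- poreclass:::.net_apply(n2, mb$X, mb$B, train = TRUE, with_cache = FALSE)
    poreclass:::.ce_loss(f$probs, y)
  }
  eps <- 1e-6
  for (nm in names(net$params)) {
    i <- sample(length(net$params[[nm]]), 1)
    up <- net$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- net$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(bwd$grads[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("grad of %s", nm))
  }
})
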