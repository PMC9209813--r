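test_that("feature and growth schedules follow the level formulas", {
  cfg <- net_config("hd", fi = 32)
  expect_equal(cfg$fl, c(32L, 64L, 128L, 256L))
  expect_equal(cfg$kl, c(8L, 16L, 32L, 64L))
  expect_equal(cfg$steps, 4L)
  expect_error(net_config("hd", fi = 20), "fi")
})

test_that("dense blocks grow channels by exactly steps x growth", {
  # fi = 32, level 1: 4 steps of 8 channels on a 32-channel input -> 64
  b <- dense_block(32, 1, net_config("hd", fi = 32), mode = "standard")
  expect_equal(b$cout, 64)
  x <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  expect_equal(dim(b$forward(x))[3], 64)
  # fi = 16, level 2: 2 steps of 16 channels on a 32-channel input -> 64
  b2 <- dense_block(32, 2, net_config("fd", fi = 16), mode = "standard")
  expect_equal(b2$cout, 64)
})

test_that("dilated dense steps split the growth into equal dilation halves", {
  cfg <- net_config("hd", fi = 32)
  b <- dense_block(8, 1, cfg, mode = "dilated")
  # each step holds a dilation-1 and a dilation-2 branch of kl/2 = 4 filters
  w1 <- b$params[["blk.s1.d1.W"]]
  w2 <- b$params[["blk.s1.d2.W"]]
  expect_equal(dim(w1$v)[4], 4L)
  expect_equal(dim(w2$v)[4], 4L)
  # level 4: k4 = 64 split as 32 + 32
  b4 <- dense_block(16, 4, cfg, mode = "dilated")
  expect_equal(dim(b4$params[["blk.s1.d1.W"]]$v)[4], 32L)
  expect_equal(dim(b4$params[["blk.s1.d2.W"]]$v)[4], 32L)
})

test_that("encoder channel ledger holds at every level", {
  cfg <- net_config("hd", fi = 16)
  for (l in 1:4) {
    b <- dense_block(cfg$fl[l], l, cfg, mode = "dilated")
    expect_equal(b$cout, 2 * cfg$fl[l])
  }
})

test_that("all four variants map any valid input to the same shape", {
  x <- matrix(runif(64 * 64), 64, 64)
  for (v in c("hd", "fd", "dd", "unet")) {
    net <- build_network(net_config(v, fi = 8), seed = 2)
    y <- net_forward(net, x)
    expect_equal(dim(y), c(64, 64))
    expect_true(all(y >= 0))  # ReLU head keeps outputs in target range
  }
  net <- build_network(net_config("hd", fi = 8, strict_shape = TRUE),
                       seed = 2)
  expect_error(net_forward(net, x), "128")
  expect_error(net_forward(build_network(net_config("hd", fi = 8), 1),
                           matrix(0, 30, 30)), "divisible")
})

test_that("parameter counts are deterministic and ordered as expected", {
  n1 <- count_parameters(build_network(net_config("hd", fi = 16), seed = 1))
  n2 <- count_parameters(build_network(net_config("hd", fi = 16), seed = 9))
  expect_identical(n1, n2)
  # the multi-rate dilated baseline is the parameter-hungry one
  nd <- count_parameters(build_network(net_config("dd", fi = 16), seed = 1))
  expect_lte(n1, nd)
  # parameters strictly increase with the initial feature count
  n8 <- count_parameters(build_network(net_config("hd", fi = 8), seed = 1))
  expect_lt(n8, n1)
})

test_that("identical seeds build identical networks", {
  a <- build_network(net_config("hd", fi = 8), seed = 5)
  b <- build_network(net_config("hd", fi = 8), seed = 5)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(net_forward(a, x), net_forward(b, x))
})

test_that("removing dilation shrinks the bottleneck receptive field", {
  rf_hd <- receptive_field(net_config("hd", fi = 16))
  rf_plain <- receptive_field(net_config("fd", fi = 16))
  expect_gt(rf_hd, rf_plain)
  rf_dd <- receptive_field(net_config("dd", fi = 16))
  expect_gt(rf_dd, rf_hd)
})

test_that("network gradients agree with finite differences", {
  pk <- asNamespace("patkit")
  net <- build_network(net_config("hd", fi = 8), seed = 3)
  xb <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  yb <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  g <- net$graph(xb, training = TRUE)
  lg <- pk$composite_loss_grad(yb, g$out$v)
  pk$zero_grads(net$params)
  pk$ag_backward(g$tape, g$out, lg$grad)
  lossf <- function() {
    gg <- net$graph(xb, training = TRUE)
    pk$composite_loss_grad(yb, gg$out$v)$loss
  }
  set.seed(17)
  for (nm in sample(names(net$params), 6)) {
    p <- net$params[[nm]]
    i <- sample(length(p$v), 1)
    v0 <- p$v[i]; eps <- 1e-5
    p$v[i] <- v0 + eps; lp <- lossf()
    p$v[i] <- v0 - eps; lm <- lossf()
    p$v[i] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - p$g[i]) / max(1e-7, abs(num) + abs(p$g[i])),
              1e-4)
  }
})
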