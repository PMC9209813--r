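test_that("the 90:5:5 split produces the stock set sizes", {
  s <- split_dataset(1500, seed = 1)
  expect_equal(lengths(s), c(train = 1350L, val = 75L, test = 75L))
  s2 <- split_dataset(500, seed = 1)
  expect_equal(lengths(s2), c(train = 450L, val = 25L, test = 25L))
  # disjoint cover of all indices
  expect_setequal(c(s$train, s$val, s$test), 1:1500)
  expect_length(intersect(s$train, s$test), 0)
  expect_length(intersect(s$train, s$val), 0)
  expect_identical(split_dataset(100, seed = 7), split_dataset(100, seed = 7))
  expect_error(split_dataset(100, ratios = c(80, 10, 5)), "sum to 100")
  expect_error(split_dataset(10), "n >= 20")
})

test_that("the plateau scheduler halves the rate after the patience window", {
  pk <- asNamespace("patkit")
  sch <- pk$plateau_scheduler(0.001, factor = 0.5, patience = 5,
                              min_lr = 1e-6)
  lrs <- vapply(rep(1, 12), sch$step, numeric(1))  # flat validation loss
  # first value establishes the best; halving lands after 5 stalled epochs
  expect_equal(lrs, c(rep(0.001, 5), rep(5e-4, 5), rep(2.5e-4, 2)))
  # improvement resets the wait counter
  sch2 <- pk$plateau_scheduler(0.001, patience = 2)
  expect_equal(sch2$step(1), 0.001)
  expect_equal(sch2$step(0.5), 0.001)
  expect_equal(sch2$step(0.6), 0.001)
  expect_equal(sch2$step(0.6), 5e-4)
  # learning-rate floor
  sch3 <- pk$plateau_scheduler(2e-6, patience = 1, min_lr = 1e-6)
  sch3$step(1); sch3$step(1); sch3$step(1); sch3$step(1)
  expect_gte(sch3$lr, 1e-6)
})

tiny_data <- function(n, seed, size = 16) {
  set.seed(seed)
  Y <- array(runif(size * size * n), c(size, size, n))
  X <- array(pmin(1, pmax(0, Y + rnorm(size * size * n, sd = 0.2))),
             dim(Y))
  list(X = X, Y = Y)
}

test_that("one epoch of training records history and leaves the rate alone", {
  d <- tiny_data(4, seed = 1)
  net <- build_network(net_config("hd", fi = 8), seed = 1)
  fit <- train_network(net, d, train_config(epochs = 1, seed = 1))
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$history$lr, 0.001)
  expect_true(is.finite(fit$history$train_loss))
  expect_error(train_network(net, list(X = array(0, c(16, 16, 0)),
                                       Y = array(0, c(16, 16, 0))),
                             train_config(epochs = 1)),
               "empty")
})

test_that("training is deterministic and reduces the loss on a simple task", {
  d <- tiny_data(8, seed = 2)
  run <- function() {
    net <- build_network(net_config("hd", fi = 8), seed = 2)
    train_network(net, d, train_config(epochs = 4, seed = 2))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
})

test_that("repeated resplit cross-validation yields a metrics table per variant", {
  d <- tiny_data(24, seed = 3)
  tc <- train_config(epochs = 1, k_repeats = 2, seed = 5)
  cv <- cross_validate(d, c("hd", "unet"), tc, fi = 8)
  expect_equal(nrow(cv$table), 2L)
  expect_equal(cv$table$variant, c("hd", "unet"))
  expect_true(all(c("pcc_mean", "pcc_sd", "psnr_mean", "psnr_sd",
                    "ssim_mean", "ssim_sd", "mae_mean", "mae_sd")
                  %in% names(cv$table)))
  expect_true(all(is.finite(cv$table$psnr_mean)))
  cv2 <- cross_validate(d, c("hd", "unet"), tc, fi = 8)
  expect_identical(cv$table, cv2$table)
  expect_error(cross_validate(d, "hd", train_config(k_repeats = 1)),
               "k_repeats")
})
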