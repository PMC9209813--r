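test_that("pixel mean absolute error matches a direct summation oracle", {
  expect_equal(mae_loss(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(mae_loss(matrix(1, 3, 3), matrix(0, 3, 3)), 1)
  set.seed(1)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  expect_equal(mae_loss(a, b), sum(abs(a - b)) / 16)
  expect_error(mae_loss(a, matrix(0, 2, 2)), "shapes differ")
})

test_that("Fourier MAE matches the brute-force DFT oracle", {
  set.seed(2)
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  ref <- mean(Mod(dft2_oracle(a) - dft2_oracle(b)))
  expect_lt(abs(fmae_loss(a, b) - ref) / ref, 1e-10)
  expect_equal(fmae_loss(a, a), 0)
})

test_that("a constant image difference puts all Fourier mass at DC", {
  set.seed(3)
  a <- matrix(runif(144), 12)
  cc <- 0.37
  # |N * c| / N = c exactly, pinning the unnormalized DFT convention
  expect_equal(fmae_loss(a, a + cc), cc, tolerance = 1e-12)
})

test_that("the composite loss combines its terms with the stock weights", {
  set.seed(4)
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  expect_equal(composite_loss(a, b, k2 = 0), mae_loss(a, b))
  expect_equal(composite_loss(a, b),
               mae_loss(a, b) + 0.001 * fmae_loss(a, b))
  expect_equal(composite_loss(a, a), 0)
  # 1-homogeneous under joint scaling
  expect_equal(composite_loss(3 * a, 3 * b), 3 * composite_loss(a, b))
})

test_that("the analytic loss gradient matches finite differences", {
  pk <- asNamespace("patkit")
  set.seed(5)
  yg <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  yp <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  lg <- pk$composite_loss_grad(yg, yp)
  for (i in sample(length(yp), 6)) {
    eps <- 1e-7
    v0 <- yp[i]
    yp[i] <- v0 + eps; lp <- pk$composite_loss_grad(yg, yp)$loss
    yp[i] <- v0 - eps; lm <- pk$composite_loss_grad(yg, yp)$loss
    yp[i] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - lg$grad[i]) / max(1e-8, abs(num)), 1e-4)
  }
})

test_that("image-quality metrics hit their closed-form anchors", {
  set.seed(6)
  a <- matrix(runif(256), 16)
  expect_equal(pcc(a, a), 1)
  expect_equal(pcc(a, 1 - a), -1)
  expect_equal(ssim_index(a, a), 1)
  expect_equal(psnr(a, a), 100)           # declared cap, not infinity
  # mse 0.01 at data range 1 -> 20 dB
  b <- a + 0.1
  expect_equal(psnr(a, b), 20, tolerance = 1e-10)
  expect_true(is.na(pcc(matrix(1, 4, 4), a[1:4, 1:4])))
})

test_that("pair evaluation summarizes per-image metrics and flags degenerates", {
  set.seed(7)
  yg <- array(runif(16 * 16 * 3), c(16, 16, 3))
  m <- evaluate_pairs(yg, yg)
  expect_equal(m$summary$mean[m$summary$metric == "pcc"], 1)
  expect_equal(m$summary$mean[m$summary$metric == "ssim"], 1)
  expect_equal(m$summary$mean[m$summary$metric == "mae"], 0)
  yp <- yg
  yp[, , 2] <- 0.5  # constant prediction: undefined correlation
  expect_warning(m2 <- evaluate_pairs(yg, yp), "undefined PCC")
  expect_equal(m2$n_undefined_pcc, 1L)
  expect_equal(m2$summary$mean[m2$summary$metric == "pcc"], 1)
})
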