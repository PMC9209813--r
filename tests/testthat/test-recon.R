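test_that("vectorized delay-and-sum matches the double-loop oracle", {
  g <- image_grid(410, 410, 0.2)
  ph <- gen_point_phantom(g, 3, seed = 2)
  scan <- scan_from_positions(20, 1, 37)
  sino <- simulate_sinogram(ph, scan, ust_transducer(2.25, 0.7),
                            snr_db = 40, seed = 3)
  out_grid <- recon_grid(32)
  img <- das_reconstruct(sino, out_grid)
  co <- patkit:::grid_coords(out_grid)
  pix <- expand.grid(x = co$x, y = co$y)
  ref <- das_oracle(sino$values, scan$x, scan$y, pix$x, pix$y,
                    1500e3, sino$dt)
  expect_lt(max(abs(img$values - matrix(ref, 32, 32))) /
              max(abs(ref)), 1e-9)
})

test_that("a dense noiseless scan localizes a point source to one pixel", {
  g <- image_grid(410, 410, 0.2)
  co <- patkit:::grid_coords(g)
  v <- matrix(0, g$nx, g$ny)
  v[which.min(abs(co$x - 7)), which.min(abs(co$y + 4))] <- 1
  p0 <- patkit:::new_pressure_map(g, v)
  scan <- scan_from_positions(4800, 1, 37)
  sino <- simulate_sinogram(p0, scan, ust_transducer(2.25, 0.7),
                            snr_db = Inf)
  img <- das_reconstruct(sino)
  pk <- which(abs(img$values) == max(abs(img$values)), arr.ind = TRUE)
  rco <- patkit:::grid_coords(recon_grid())
  expect_lte(abs(rco$x[pk[1]] - 7), recon_grid()$dx)
  expect_lte(abs(rco$y[pk[2]] + 4), recon_grid()$dx)
})

test_that("an all-zero sinogram reconstructs to the all-zero image", {
  g <- image_grid(410, 410, 0.2)
  z <- patkit:::new_pressure_map(g, matrix(0, g$nx, g$ny))
  sino <- simulate_sinogram(z, scan_from_positions(10, 1, 37),
                            ust_transducer(2.25, 0.7), snr_db = Inf)
  expect_true(all(das_reconstruct(sino)$values == 0))
})

test_that("delay-and-sum rejects an inconsistent medium", {
  g <- image_grid(410, 410, 0.2)
  ph <- gen_point_phantom(g, 1, seed = 1)
  sino <- simulate_sinogram(ph, scan_from_positions(4, 1, 37),
                            ust_transducer(2.25, 0.7), snr_db = Inf)
  expect_error(das_reconstruct(sino, medium = pat_medium(1400)),
               "inconsistent")
})

test_that("min-max normalization preserves bipolar structure as an offset", {
  m <- matrix(c(-2, 0, 2, 0), 2, 2)
  out <- normalize_image(m)
  expect_equal(sort(unique(as.vector(out))), c(0, 0.5, 1))
  r <- matrix(rnorm(64), 8, 8)
  rn <- normalize_image(r)
  expect_identical(min(rn), 0)
  expect_identical(max(rn), 1)
  # already-normalized image is unchanged
  expect_equal(normalize_image(rn), rn)
  expect_error(normalize_image(matrix(1, 4, 4)), "constant")
})

test_that("training pairs follow the stock acquisition protocol", {
  p <- pat_preset("1ust")
  ph <- gen_point_phantom(p$grid, 5, seed = 21)
  pr <- make_pair(ph, p, seed = 31)
  expect_true(pr$n_positions %in% seq(10, 50, 10))
  expect_equal(dim(pr$X$values), c(128L, 128L))
  expect_equal(dim(pr$Y$values), c(128L, 128L))
  expect_equal(pr$snr_db, 40)
  expect_equal(range(pr$X$values), c(0, 1))
  expect_equal(range(pr$Y$values), c(0, 1))
  pr2 <- make_pair(ph, p, seed = 31)
  expect_identical(pr$X$values, pr2$X$values)
  expect_identical(pr$Y$values, pr2$Y$values)
})

test_that("the eight-transducer preset uses 240 input and 1600 truth positions", {
  p <- pat_preset("8ust")
  ph <- gen_vessel_phantom(p$grid, seed = 41)
  pr <- make_pair(ph, p, seed = 51)
  expect_equal(pr$n_positions, 240L)
  expect_gte(pr$snr_db, 10)
  expect_lte(pr$snr_db, 20)
  expect_equal(p$gt_positions, 1600L)
  expect_equal(dim(pr$X$values), c(128L, 128L))
})

test_that("datasets assemble, save, and reload losslessly", {
  d <- build_dataset("1ust", 2, seed = 3, gt_positions = 600)
  expect_equal(dim(d$X), c(128, 128, 2))
  path <- tempfile(fileext = ".rds")
  save_dataset(d, path)
  d2 <- load_dataset(path)
  expect_identical(d$X, d2$X)
  expect_identical(d$Y, d2$Y)
  expect_identical(d$meta, d2$meta)
})
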