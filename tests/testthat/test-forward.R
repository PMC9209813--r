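test_that("scan planning reproduces the stock position counts", {
  expect_equal(plan_scan(5, 10)$n_positions, 50L)
  expect_equal(plan_scan(480, 10)$n_positions, 4800L)
  s8 <- plan_scan(0.3, 2000, n_ust = 8, averaging_factor = 2.5)
  expect_equal(s8$n_positions, 240L)
  expect_equal(s8$positions_per_ust, 30L)
  s8gt <- plan_scan(1.5, 2000, n_ust = 8, averaging_factor = 2.5)
  expect_equal(s8gt$n_positions, 1200L)
  expect_equal(s8gt$positions_per_ust, 150L)
  expect_error(plan_scan(0.01, 10), "no pulses")
})

test_that("multi-transducer sectors partition the circle equally", {
  s <- plan_scan(1.5, 2000, n_ust = 8, averaging_factor = 2.5)
  sector <- 2 * pi / 8
  for (u in 1:8) {
    ang <- s$angles[(u - 1) * 150 + 1:150]
    expect_true(all(ang >= (u - 1) * sector - 1e-12 & ang < u * sector))
  }
  expect_equal(sqrt(s$x^2 + s$y^2), rep(37, 1200))
})

test_that("transducer impulse response has the nominal spectral shape", {
  dt <- 40e-9; nt <- 1500
  tr <- ust_transducer(2.25, 0.7)
  h <- transducer_eir(tr, dt, nt)
  H <- Mod(fft(c(h, rep(0, nt - length(h)))))
  freqs <- (seq_len(nt) - 1) / (nt * dt)
  half <- freqs <= 1 / (2 * dt)
  pk <- which.max(H[half])
  df <- freqs[2] - freqs[1]
  expect_lt(abs(freqs[pk] - 2.25e6), df + 1e-9)
  # -6 dB fractional bandwidth = 0.7 => full width 1.575 MHz
  above <- which(H[half] >= max(H[half]) / 2)
  width <- (max(above) - min(above)) * df
  expect_lt(abs(width - 1.575e6) / 1.575e6, 0.05)
  expect_identical(transducer_eir(ust_transducer(2.25, ideal = TRUE), dt), 1)
  expect_error(transducer_eir(ust_transducer(15, 0.7), dt), "Nyquist")
})

point_map <- function(grid, x_mm, y_mm) {
  co <- patkit:::grid_coords(grid)
  v <- matrix(0, grid$nx, grid$ny)
  v[which.min(abs(co$x - x_mm)), which.min(abs(co$y - y_mm))] <- 1
  patkit:::new_pressure_map(grid, v)
}

test_that("point-source arrival times follow the time of flight", {
  g <- image_grid(410, 410, 0.2)
  p0 <- point_map(g, 0, 0)
  scan <- scan_from_positions(4, 1, 37)
  sino <- simulate_sinogram(p0, scan, ust_transducer(2.25, 0.7),
                            snr_db = Inf)
  for (j in 1:4) {
    idx <- arrival_index(sino$values[, j])
    expect_lte(abs(idx - round(37e-3 / 1500 / 40e-9)), 2)
  }
  # translation covariance: shifted source arrives at |x - r_d| / c
  p1 <- point_map(g, 8, -5)
  sino1 <- simulate_sinogram(p1, scan, ust_transducer(2.25, 0.7),
                             snr_db = Inf)
  co <- patkit:::grid_coords(g)
  sx <- co$x[which.min(abs(co$x - 8))]
  sy <- co$y[which.min(abs(co$y + 5))]
  for (j in 1:4) {
    d <- sqrt((sx - scan$x[j])^2 + (sy - scan$y[j])^2)
    idx <- arrival_index(sino1$values[, j])
    expect_lte(abs(idx - round(d * 1e-3 / 1500 / 40e-9)), 2)
  }
})

test_that("the forward operator is linear and maps zero to zero", {
  g <- image_grid(410, 410, 0.2)
  pa <- point_map(g, 5, 2)
  pb <- point_map(g, -6, -9)
  pab <- patkit:::new_pressure_map(g, pa$values + pb$values)
  scan <- scan_from_positions(8, 1, 37)
  tr <- ust_transducer(2.25, 0.7, aperture_mm = 13)
  sa <- simulate_sinogram(pa, scan, tr, snr_db = Inf)
  sb <- simulate_sinogram(pb, scan, tr, snr_db = Inf)
  sab <- simulate_sinogram(pab, scan, tr, snr_db = Inf)
  expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-12)
  z <- patkit:::new_pressure_map(g, matrix(0, g$nx, g$ny))
  sz <- simulate_sinogram(z, scan, tr, snr_db = Inf)
  expect_true(all(sz$values == 0))
  expect_error(simulate_sinogram(z, scan, tr, snr_db = 40), "all-zero")
})

test_that("additive noise hits the requested rms SNR and is seeded", {
  x <- matrix(sin(seq(0, 40 * pi, length.out = 4000)), 400)
  y <- add_noise(x, 40, seed = 5)
  snr <- 20 * log10(sqrt(mean(x^2)) / sqrt(mean((y - x)^2)))
  expect_lt(abs(snr - 40), 0.5)
  expect_identical(add_noise(x, 40, seed = 5), y)
  expect_false(identical(add_noise(x, 40, seed = 6), y))
  expect_identical(add_noise(x, Inf, seed = 1), x)
  expect_error(add_noise(matrix(0, 3, 3), 40, 1), "all-zero")
})

test_that("doubling aperture sub-elements changes the sinogram by < 1% rms", {
  g <- image_grid(410, 410, 0.2)
  ph <- gen_point_phantom(g, 3, seed = 8)
  scan <- scan_from_positions(6, 1, 37)
  tr <- ust_transducer(2.25, 0.7, aperture_mm = 13)
  s1 <- simulate_sinogram(ph, scan, tr, snr_db = Inf)   # default count
  s2 <- simulate_sinogram(ph, scan, tr, snr_db = Inf, n_subelements = 66)
  rel <- sqrt(mean((s1$values - s2$values)^2)) / sqrt(mean(s1$values^2))
  expect_lt(rel, 0.01)
})

test_that("a finite aperture degrades tangential resolution off-center", {
  g <- image_grid(410, 410, 0.2)
  scan <- scan_from_positions(240, 1, 37)
  tr_ap <- ust_transducer(2.25, 0.7, aperture_mm = 13)
  fwhm <- vapply(c(3, 9, 15), function(r_mm) {
    p0 <- point_map(g, r_mm, 0)
    sino <- simulate_sinogram(p0, scan, tr_ap, snr_db = Inf)
    tangential_fwhm(das_reconstruct(sino), c(r_mm, 0), recon_grid()$dx)
  }, numeric(1))
  expect_true(all(diff(fwhm) > 0))
  # and the ideal point detector does not show that growth at the far point
  p0 <- point_map(g, 15, 0)
  sino_pt <- simulate_sinogram(p0, scan, ust_transducer(2.25, 0.7),
                               snr_db = Inf)
  fwhm_pt <- tangential_fwhm(das_reconstruct(sino_pt), c(15, 0),
                             recon_grid()$dx)
  expect_lt(fwhm_pt, fwhm[3])
})
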