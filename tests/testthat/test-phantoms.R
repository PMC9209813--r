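grid_1ust <- image_grid(410, 410, 0.2)

test_that("point phantoms place the requested number of separated targets", {
  ph <- gen_point_phantom(grid_1ust, 5, seed = 1)
  expect_equal(count_components(ph$values > 0), 5)
  # all mass inside the 40 mm imaging disc
  co <- patkit:::grid_coords(grid_1ust)
  nz <- which(ph$values > 0, arr.ind = TRUE)
  expect_true(all(co$x[nz[, 1]]^2 + co$y[nz[, 2]]^2 <= 20^2))
  # held-out nine-point test shape
  ph9 <- gen_point_phantom(grid_1ust, 9, seed = 4)
  expect_equal(count_components(ph9$values > 0), 9)
})

test_that("empty point phantom is the all-zero map", {
  ph <- gen_point_phantom(grid_1ust, 0, seed = 1)
  expect_true(all(ph$values == 0))
})

test_that("impossible point placement raises a placement error", {
  expect_error(
    gen_point_phantom(grid_1ust, 500, seed = 1, diameter_mm = 4,
                      max_tries = 200),
    "placement")
})

test_that("phantom generators are pure functions of their seed", {
  for (fam in c("points", "triangle", "vessel")) {
    a <- gen_phantom(fam, grid_1ust, seed = 11)
    b <- gen_phantom(fam, grid_1ust, seed = 11)
    expect_identical(a$values, b$values)
    c <- gen_phantom(fam, grid_1ust, seed = 12)
    expect_gt(mean(a$values != c$values), 0)
  }
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_vessel_phantom(grid_1ust, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("triangle outlines stay inside the imaging disc", {
  for (s in 1:5) {
    ph <- gen_triangle_phantom(grid_1ust, seed = s)
    expect_gt(sum(ph$values > 0), 0)
    co <- patkit:::grid_coords(grid_1ust)
    nz <- which(ph$values > 0, arr.ind = TRUE)
    expect_true(all(co$x[nz[, 1]]^2 + co$y[nz[, 2]]^2 <= 20^2))
  }
})

test_that("triangle rasterization is invariant under a full rotation", {
  m1 <- patkit:::draw_triangle(grid_1ust, c(3, -2), 15, 0.7, 0.2)
  m2 <- patkit:::draw_triangle(grid_1ust, c(3, -2), 15, 0.7 + 2 * pi, 0.2)
  # identical pixel sets within rasterization tolerance
  expect_lt(mean((m1 > 0) != (m2 > 0)), 1e-4)
})

test_that("triangle size bounds beyond the disc are a configuration error", {
  expect_error(gen_triangle_phantom(grid_1ust, seed = 1,
                                    side_range_mm = c(40, 80)),
               "exceed")
})

test_that("vessel phantoms are connected, sparse, and seed-sensitive", {
  ph <- gen_vessel_phantom(grid_1ust, seed = 1)
  mask <- ph$values > 0
  disc_px <- sum(patkit:::fov_mask(grid_1ust))
  frac <- sum(mask) / disc_px
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.10)
  # the main trunk dominates: largest component holds most of the mass
  expect_lte(count_components(mask), 8)
  a <- gen_vessel_phantom(grid_1ust, seed = 2)
  expect_gt(mean((ph$values > 0) != (a$values > 0)), 0.01 * frac)
  zero <- gen_vessel_phantom(grid_1ust, seed = 1, magnitude_scale = 0)
  expect_true(all(zero$values == 0))
})

test_that("dataset-scale generation completes without placement failures", {
  # thinned stand-in for the stock 1500/500-phantom runs
  for (s in 1:15) {
    fam <- c("points", "triangle", "vessel")[(s %% 3) + 1]
    ph <- gen_phantom(fam, grid_1ust, seed = 5000 + s)
    expect_gt(sum(ph$values > 0), 0)
  }
})
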