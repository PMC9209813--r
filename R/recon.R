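#' Reconstruction output grid
#'
#' The network input/output format is a 128 x 128 image spanning the 40 mm
#' imaging region (pixel pitch 0.3125 mm).
#'
#' @param n Pixels per side.
#' @param fov_mm Field of view in mm.
#' @return A `pat_grid` covering the field of view.
#' @export
recon_grid <- function(n = 128, fov_mm = 40) {
  image_grid(n, n, fov_mm / n, fov_mm = fov_mm)
}

new_recon_image <- function(values, pitch, normalized = FALSE) {
  structure(list(values = values, pitch = pitch, normalized = normalized),
            class = "pat_image")
}

#' @export
print.pat_image <- function(x, ...) {
  cat(sprintf("<pat_image> %d x %d px, pitch %.4g mm, range [%.3g, %.3g]%s\n",
              nrow(x$values), ncol(x$values), x$pitch,
              min(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Delay-and-sum beamforming
#'
#' Conventional delay-and-sum: every pixel accumulates, over all detector
#' positions, the A-line sample at the time of flight `|x - r_d| / c`,
#' with linear interpolation between time samples and no apodization.
#' Delays outside the recorded window contribute zero.  The result is a
#' bipolar (unnormalized) cross-sectional image.
#'
#' @param sinogram A `pat_sinogram`.
#' @param grid_out Output grid, default [recon_grid()] (128 x 128, 40 mm).
#' @param medium A [pat_medium()]; must match the simulation medium.
#' @return A `pat_image` (bipolar, unnormalized).
#' @export
das_reconstruct <- function(sinogram, grid_out = recon_grid(),
                            medium = sinogram$medium) {
  stopifnot(inherits(sinogram, "pat_sinogram"))
  if (!isTRUE(all.equal(medium$c, sinogram$medium$c)))
    stop("medium inconsistent with the recorded sinogram")
  co <- grid_coords(grid_out)
  pix <- expand.grid(x = co$x, y = co$y)
  img <- cpp_das(sinogram$values, sinogram$geometry$x, sinogram$geometry$y,
                 pix$x, pix$y, medium$c * 1e3, sinogram$dt)
  new_recon_image(matrix(img, grid_out$nx, grid_out$ny), grid_out$dx)
}

#' Min-max normalization preserving bipolar structure
#'
#' Rescales `(A - Amin) / (Amax - Amin)` to the range 0 to 1.  Zero
#' pressure maps to `-Amin / (Amax - Amin)`, so the bipolar information is
#' kept as an offset rather than clipped.
#'
#' @param image A `pat_image` (or bare matrix).
#' @return A normalized `pat_image` with min exactly 0 and max exactly 1.
#' @export
normalize_image <- function(image) {
  v <- if (inherits(image, "pat_image")) image$values else image
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("cannot normalize a constant image (Amax == Amin)")
  out <- (v - lo) / (hi - lo)
  if (inherits(image, "pat_image"))
    new_recon_image(out, image$pitch, normalized = TRUE)
  else out
}

#' Simulate a (sparse input, dense ground truth) training pair
#'
#' The input `X` is the normalized delay-and-sum reconstruction of a
#' sparse, finite-aperture, noisy scan; the ground truth `Y` is the
#' normalized reconstruction of a dense, point-detector, noise-free scan
#' of the same phantom.  For the `"1ust"` preset the sparse scan uses
#' 10-50 positions (scan time 1-5 s at 10 Hz) against 4800 ground-truth
#' positions; for `"8ust"`, 240 positions against 1600.
#'
#' @param p0 A `pat_pressure` phantom on the preset grid.
#' @param preset A [pat_preset()] list (or its name).
#' @param scan_time Input scan time in s; `NULL` draws one from the
#'   preset's stock values.
#' @param seed Integer seed controlling the scan-time/SNR draw and noise.
#' @return List with `X` and `Y` (`pat_image`, normalized) plus the
#'   realized `n_positions`, `scan_time` and `snr_db`.
#' @export
make_pair <- function(p0, preset, scan_time = NULL, seed = NULL) {
  if (is.character(preset)) preset <- pat_preset(preset)
  draws <- with_seed(seed, {
    st <- if (is.null(scan_time)) sample(preset$scan_times, 1) else scan_time
    list(scan_time = st,
         snr_db = runif(1, preset$snr_db[1], preset$snr_db[2]),
         noise_seed = sample.int(.Machine$integer.max, 1))
  })
  sparse <- plan_scan(draws$scan_time, preset$prr, preset$n_ust,
                      preset$scan_radius, preset$averaging_factor)
  dense <- scan_from_positions(preset$gt_positions, preset$n_ust,
                               preset$scan_radius)
  sino_x <- simulate_sinogram(p0, sparse, preset$transducer,
                              snr_db = draws$snr_db, seed = draws$noise_seed,
                              dt = preset$dt, n_time = preset$n_time)
  sino_y <- simulate_sinogram(p0, dense, preset$gt_transducer,
                              snr_db = Inf,
                              dt = preset$dt, n_time = preset$n_time)
  list(X = normalize_image(das_reconstruct(sino_x)),
       Y = normalize_image(das_reconstruct(sino_y)),
       n_positions = sparse$n_positions,
       scan_time = draws$scan_time, snr_db = draws$snr_db)
}

#' Generate a paired training dataset
#'
#' Cycles through the preset's phantom families, simulating one
#' (sparse input, dense ground truth) pair per phantom.
#'
#' @param preset A [pat_preset()] list or name.
#' @param n Number of pairs.
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param gt_positions Optional override of the ground-truth detector
#'   count (smaller values speed up exploratory runs).
#' @return A `pat_dataset`: arrays `X` and `Y` of shape `[128, 128, n]`
#'   plus per-pair metadata.
#' @export
build_dataset <- function(preset, n, seed = 1, gt_positions = NULL) {
  if (is.character(preset)) preset <- pat_preset(preset)
  if (!is.null(gt_positions)) preset$gt_positions <- as.integer(gt_positions)
  fam <- rep_len(preset$families, n)
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max, 2 * n), n))
  g <- recon_grid()
  X <- array(0, c(g$nx, g$ny, n)); Y <- array(0, c(g$nx, g$ny, n))
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- gen_phantom(fam[i], preset$grid, seed = seeds[i, 1])
    pr <- make_pair(p0, preset, seed = seeds[i, 2])
    X[, , i] <- pr$X$values
    Y[, , i] <- pr$Y$values
    meta[[i]] <- list(family = fam[i], n_positions = pr$n_positions,
                      scan_time = pr$scan_time, snr_db = pr$snr_db)
  }
  structure(list(X = X, Y = Y, meta = meta, preset = preset$name,
                 seed = seed, schema = 1L),
            class = "pat_dataset")
}

#' @export
print.pat_dataset <- function(x, ...) {
  cat(sprintf("<pat_dataset> %d pairs of %d x %d images (preset %s, seed %s)\n",
              dim(x$X)[3], dim(x$X)[1], dim(x$X)[2], x$preset,
              format(x$seed)))
  invisible(x)
}
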