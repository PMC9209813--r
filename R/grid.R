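#' Define a square computational grid
#'
#' The simulation domain is an `nx` x `ny` pixel grid with spacing `dx`
#' (mm/pixel), centered on the scan axis.  The two stock configurations are
#' 82 x 82 mm at 0.2 mm/pixel (single-transducer system) and 82 x 82 mm at
#' 0.1 mm/pixel (eight-transducer system); the imaging region proper is a
#' centered disc of 40 mm diameter inside this domain.
#'
#' @param nx,ny Pixel counts along x and y.
#' @param dx Pixel spacing in mm/pixel (isotropic).
#' @param fov_mm Diameter (mm) of the centered circular imaging region.
#' @return An object of class `pat_grid` with fields `nx`, `ny`, `dx`,
#'   `extent` (physical size in mm) and `fov_mm`.
#' @examples
#' g <- image_grid(410, 410, 0.2)
#' g$extent  # 82 mm
#' @export
image_grid <- function(nx, ny, dx, fov_mm = 40) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, fov_mm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 extent = c(nx * dx, ny * dx), fov_mm = fov_mm),
            class = "pat_grid")
}

#' @export
print.pat_grid <- function(x, ...) {
  cat(sprintf("<pat_grid> %d x %d px, %.3g mm/px (%.3g x %.3g mm), FOV %.3g mm\n",
              x$nx, x$ny, x$dx, x$extent[1], x$extent[2], x$fov_mm))
  invisible(x)
}

# Pixel-center coordinates in mm, origin at the grid center.
grid_coords <- function(grid) {
  x <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$dx
  y <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$dx
  list(x = x, y = y)
}

# Logical mask of the centered circular imaging region.
fov_mask <- function(grid) {
  co <- grid_coords(grid)
  outer(co$x^2, co$y^2, `+`) <= (grid$fov_mm / 2)^2
}

#' Acoustic medium description
#'
#' Both stock configurations use a homogeneous, lossless medium with a speed
#' of sound of 1500 m/s.
#'
#' @param c Speed of sound in m/s.
#' @param homogeneous Logical; only homogeneous media are supported.
#' @return A `pat_medium` object.
#' @export
pat_medium <- function(c = 1500, homogeneous = TRUE) {
  stopifnot(c > 0, isTRUE(homogeneous))
  structure(list(c = c, homogeneous = homogeneous), class = "pat_medium")
}

#' Stock system presets
#'
#' Bundles the simulation parameters of the two circular-scan systems:
#'
#' * `"1ust"`: one 2.25 MHz unfocused transducer (70% nominal bandwidth,
#'   13 mm aperture), 10 Hz pulse repetition rate, 0.2 mm/pixel grid,
#'   sparse scans of 10-50 positions (1-5 s scan time), 40 dB SNR, ground
#'   truth from 4800 point-detector positions.
#' * `"8ust"`: eight 5 MHz transducers, 2000 Hz pulse repetition rate,
#'   0.1 mm/pixel grid, fast scans of 240 positions (0.3 s), SNR drawn from
#'   10-20 dB, ground truth from 1600 point-detector positions.
#'
#' @param name `"1ust"` or `"8ust"`.
#' @return A named list of preset parameters (grid, transducer, scan radius,
#'   timing, SNR policy, ground-truth detector count, dataset size).
#' @export
pat_preset <- function(name = c("1ust", "8ust")) {
  name <- match.arg(name)
  if (name == "1ust") {
    list(name = "1ust",
         grid = image_grid(410, 410, 0.2),
         n_ust = 1L, prr = 10, averaging_factor = 1,
         scan_radius = 37,
         transducer = ust_transducer(fc_mhz = 2.25, bandwidth = 0.7,
                                     aperture_mm = 13),
         gt_transducer = ust_transducer(fc_mhz = 2.25, bandwidth = 0.7,
                                        aperture_mm = 0),
         dt = 40e-9, n_time = 1500L,
         snr_db = c(40, 40),
         gt_positions = 4800L,
         scan_times = 1:5,              # s; 10..50 positions at 10 Hz
         n_phantoms = 1500L,
         families = c("points", "triangle", "vessel"))
  } else {
    list(name = "8ust",
         grid = image_grid(820, 820, 0.1),
         n_ust = 8L, prr = 2000, averaging_factor = 2.5,
         scan_radius = 37,
         transducer = ust_transducer(fc_mhz = 5, bandwidth = 0.7,
                                     aperture_mm = 13),
         gt_transducer = ust_transducer(fc_mhz = 5, bandwidth = 0.7,
                                        aperture_mm = 0),
         dt = 40e-9, n_time = 1500L,
         snr_db = c(10, 20),
         gt_positions = 1600L,
         scan_times = 0.3,              # s; 240 positions after averaging
         n_phantoms = 500L,
         families = "vessel")
  }
}
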