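#' Ultrasound transducer description
#'
#' @param fc_mhz Central frequency in MHz (> 0).
#' @param bandwidth Fractional -6 dB bandwidth (0.7 = 70% nominal).
#' @param aperture_mm Active-element width in mm (0 = point detector).
#' @param ideal Logical; an ideal detector has no aperture and a delta
#'   impulse response (no band-limiting).
#' @return A `pat_transducer` object.
#' @export
ust_transducer <- function(fc_mhz, bandwidth = 0.7, aperture_mm = 0,
                           ideal = FALSE) {
  stopifnot(fc_mhz > 0, bandwidth > 0, bandwidth < 2, aperture_mm >= 0)
  if (ideal) aperture_mm <- 0
  structure(list(fc_mhz = fc_mhz, bandwidth = bandwidth,
                 aperture_mm = aperture_mm, ideal = ideal),
            class = "pat_transducer")
}

#' Plan a circular scan geometry
#'
#' Detector positions are laid out on the scan circle from the scan
#' duration, the laser pulse repetition rate, and the transducer count.
#' With `n_ust` transducers the circle is divided into `n_ust` equal
#' angular sectors and each transducer sweeps its own sector, so
#' `positions_per_ust = round(duration * prr / averaging_factor / n_ust)`.
#' The eight-transducer system bins repeated pulses in hardware; its preset
#' uses `averaging_factor = 2.5` so the planned counts match the acquired
#' A-line counts (240 positions for a 0.3 s scan, 1200 for 1.5 s).
#'
#' @param duration Scan time in s (> 0).
#' @param prr Pulse repetition rate in Hz (> 0).
#' @param n_ust Number of transducers (>= 1).
#' @param scan_radius Scan-circle radius in mm.
#' @param averaging_factor Pulses averaged per stored A-line.
#' @return A `pat_scan` with detector angles and coordinates.
#' @examples
#' plan_scan(5, 10)$n_positions        # 50
#' plan_scan(480, 10)$n_positions      # 4800
#' plan_scan(0.3, 2000, n_ust = 8, averaging_factor = 2.5)$n_positions  # 240
#' @export
plan_scan <- function(duration, prr, n_ust = 1, scan_radius = 37,
                      averaging_factor = 1) {
  stopifnot(duration > 0, prr > 0, n_ust >= 1, averaging_factor > 0)
  if (duration * prr < 1) stop("no pulses fired: duration * prr < 1")
  per_ust <- round(duration * prr / averaging_factor / n_ust)
  if (per_ust < 1) stop("no positions per transducer at these settings")
  scan_from_positions(per_ust * n_ust, n_ust, scan_radius,
                      duration = duration, prr = prr)
}

#' Scan geometry from an explicit position count
#'
#' @param n_positions Total detector positions (multiple of `n_ust`).
#' @param n_ust Number of transducers.
#' @param scan_radius Scan-circle radius in mm.
#' @param duration,prr Optional timing metadata.
#' @return A `pat_scan`.
#' @export
scan_from_positions <- function(n_positions, n_ust = 1, scan_radius = 37,
                                duration = NA_real_, prr = NA_real_) {
  n_positions <- as.integer(n_positions)
  n_ust <- as.integer(n_ust)
  stopifnot(n_positions >= 1, n_ust >= 1, n_positions %% n_ust == 0)
  per_ust <- n_positions %/% n_ust
  sector <- 2 * pi / n_ust
  angles <- as.vector(vapply(seq_len(n_ust), function(u) {
    (u - 1) * sector + (seq_len(per_ust) - 1) / per_ust * sector
  }, numeric(per_ust)))
  structure(list(scan_radius = scan_radius, n_ust = n_ust,
                 n_positions = n_positions, positions_per_ust = per_ust,
                 angles = angles,
                 x = scan_radius * cos(angles),
                 y = scan_radius * sin(angles),
                 duration = duration, prr = prr),
            class = "pat_scan")
}

#' @export
print.pat_scan <- function(x, ...) {
  cat(sprintf("<pat_scan> %d positions (%d UST x %d), radius %.1f mm\n",
              x$n_positions, x$n_ust, x$positions_per_ust, x$scan_radius))
  invisible(x)
}

#' Transducer electrical impulse response
#'
#' A zero-phase Gaussian-modulated sinusoid whose amplitude spectrum peaks
#' at the central frequency and whose -6 dB fractional width equals the
#' nominal fractional bandwidth.  The kernel is normalized to unit peak
#' spectral magnitude, so convolution leaves the passband amplitude
#' unchanged.  Ideal transducers get a delta kernel.
#'
#' @param transducer A [ust_transducer()].
#' @param dt Sample interval in s.
#' @param n_time Number of time samples (used for normalization).
#' @return Odd-length numeric kernel centered at its midpoint.
#' @export
transducer_eir <- function(transducer, dt, n_time = 1500) {
  if (isTRUE(transducer$ideal)) return(1)
  fc <- transducer$fc_mhz * 1e6
  if (fc >= 1 / (2 * dt))
    stop("central frequency at or above Nyquist for dt = ", dt)
  # -6 dB full width of a Gaussian amplitude spectrum = 2*sigma_f*sqrt(2 ln 2)
  sigma_f <- transducer$bandwidth * fc / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- max(3L, ceiling(4 * sigma_t / dt))
  t <- (-half:half) * dt
  h <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * t)
  # unit peak spectral magnitude on the working record length
  nfft <- max(n_time, length(h))
  h / max(Mod(fft(c(h, rep(0, nfft - length(h))))))
}

# Circular ("same") convolution of each sinogram column with a centered
# kernel, via FFT.  Signals decay well before the record end at the stock
# settings, so wrap-around is inert.
convolve_columns <- function(values, kernel) {
  if (length(kernel) == 1) return(values * kernel)
  nt <- nrow(values)
  half <- (length(kernel) - 1) / 2
  kw <- rep(0, nt)
  idx <- ((-half:half) %% nt) + 1
  kw[idx] <- kw[idx] + kernel
  H <- fft(kw)
  Re(mvfft(mvfft(values) * H, inverse = TRUE)) / nt
}

#' Add Gaussian noise at a prescribed SNR
#'
#' The SNR convention is rms-based: `snr_db = 20 log10(rms_signal/rms_noise)`
#' measured over the whole array.
#'
#' @param values Numeric array (not all zero).
#' @param snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed for reproducible noise.
#' @return `values` plus scaled white Gaussian noise.
#' @export
add_noise <- function(values, snr_db, seed = NULL) {
  if (is.infinite(snr_db)) return(values)
  rms_s <- sqrt(mean(values^2))
  if (rms_s == 0) stop("SNR undefined for an all-zero signal")
  rms_n <- rms_s / 10^(snr_db / 20)
  with_seed(seed, values + array(rnorm(length(values), sd = rms_n),
                                 dim = dim(values) %||% length(values)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a circular-scan sinogram
#'
#' For a homogeneous lossless 2D medium the pressure at a point detector is
#' `p(r_d, t) \propto d/dt [ t * M(p0)(r_d, ct) ]` where `M` is the
#' circular-mean operator.  Discretizing the initial pressure as pixel
#' sources makes `t * M(ct)` a weighted arrival-time histogram, which is
#' differentiated and convolved with the transducer impulse response.  A
#' finite aperture is modeled as a flat element tangent to the scan circle,
#' averaged over `n_subelements` sub-detectors.  Noise is added to reach
#' `snr_db` over the whole sinogram.
#'
#' @param p0 A `pat_pressure` phantom.
#' @param geometry A `pat_scan`.
#' @param transducer A [ust_transducer()].
#' @param medium A [pat_medium()].
#' @param snr_db SNR in dB (`Inf` disables noise).
#' @param seed Seed for the noise draw.
#' @param dt Time step in s.
#' @param n_time Number of time samples.
#' @param n_subelements Sub-elements spanning the aperture.
#' @return A `pat_sinogram`: `values` is `[n_time x n_positions]`.
#' @export
simulate_sinogram <- function(p0, geometry, transducer,
                              medium = pat_medium(), snr_db = Inf,
                              seed = NULL, dt = 40e-9, n_time = 1500,
                              n_subelements = 33) {
  stopifnot(inherits(p0, "pat_pressure"), inherits(geometry, "pat_scan"))
  if (geometry$n_positions < 1) stop("empty scan geometry")
  c_mm <- medium$c * 1e3  # mm/s
  nz <- which(p0$values > 0, arr.ind = TRUE)
  co <- grid_coords(p0$grid)
  if (nrow(nz)) {
    px <- co$x[nz[, 1]]; py <- co$y[nz[, 2]]
    vv <- p0$values[nz] * p0$grid$dx^2
  } else {
    if (is.finite(snr_db)) stop("SNR undefined for an all-zero phantom")
    px <- py <- vv <- numeric(0)
  }
  ap <- transducer$aperture_mm
  if (ap > 0 && n_subelements >= 1) {
    # flat element tangent to the scan circle, split into sub-segments;
    # each segment deposits its arrival-time spread as a box in time
    edges <- seq(-ap / 2, ap / 2, length.out = n_subelements + 1)
    tx <- -sin(geometry$angles); ty <- cos(geometry$angles)
    one <- rep(1, n_subelements)
    e0x <- as.vector(outer(geometry$x, one) + outer(tx, edges[-length(edges)]))
    e0y <- as.vector(outer(geometry$y, one) + outer(ty, edges[-length(edges)]))
    e1x <- as.vector(outer(geometry$x, one) + outer(tx, edges[-1]))
    e1y <- as.vector(outer(geometry$y, one) + outer(ty, edges[-1]))
    raw <- cpp_project_segments(px, py, vv, e0x, e0y, e1x, e1y,
                                c_mm, dt, as.integer(n_time))
    dim(raw) <- c(n_time, geometry$n_positions, n_subelements)
    raw <- rowMeans(raw, dims = 2)
  } else {
    raw <- cpp_project_arrivals(px, py, vv, geometry$x, geometry$y,
                                c_mm, dt, as.integer(n_time))
  }
  # time derivative (central difference) then impulse response
  nt <- nrow(raw)
  der <- (raw[c(2:nt, nt), , drop = FALSE] -
          raw[c(1, 1:(nt - 1)), , drop = FALSE]) / (2 * dt)
  der[1, ] <- 0; der[nt, ] <- 0
  eir <- transducer_eir(transducer, dt, n_time)
  sig <- convolve_columns(der, eir)
  if (is.finite(snr_db)) sig <- add_noise(sig, snr_db, seed)
  structure(list(values = sig, dt = dt, n_time = as.integer(n_time),
                 geometry = geometry, transducer = transducer,
                 medium = medium, snr_db = snr_db),
            class = "pat_sinogram")
}

#' @export
print.pat_sinogram <- function(x, ...) {
  cat(sprintf("<pat_sinogram> %d positions x %d samples, dt %.3g ns, SNR %s dB\n",
              ncol(x$values), x$n_time, x$dt * 1e9, format(x$snr_db)))
  invisible(x)
}
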