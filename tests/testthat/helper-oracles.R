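# Independent brute-force oracles used across the suite.

# Per-pixel / per-detector double-loop delay-and-sum.
das_oracle <- function(sino_vals, detx, dety, pixx, pixy, c_mm, dt) {
  np <- length(pixx)
  nt <- nrow(sino_vals)
  out <- numeric(np)
  for (p in seq_len(np)) {
    acc <- 0
    for (j in seq_along(detx)) {
      tt <- sqrt((pixx[p] - detx[j])^2 + (pixy[p] - dety[j])^2) / (c_mm * dt)
      i0 <- floor(tt)
      if (i0 < 0 || i0 >= nt - 1) next
      w <- tt - i0
      acc <- acc + sino_vals[i0 + 1, j] * (1 - w) + sino_vals[i0 + 2, j] * w
    }
    out[p] <- acc
  }
  out
}

# Direct double-sum unnormalized 2D DFT.
dft2_oracle <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  out <- matrix(0 + 0i, n1, n2)
  for (k1 in 0:(n1 - 1)) for (k2 in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (j1 in 0:(n1 - 1)) for (j2 in 0:(n2 - 1)) {
      s <- s + x[j1 + 1, j2 + 1] *
        exp(-2i * pi * (k1 * j1 / n1 + k2 * j2 / n2))
    }
    out[k1 + 1, k2 + 1] <- s
  }
  out
}

# 4-connected component count of a binary mask (queue flood fill).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(mask)) next
        q <- r2 + (c2 - 1) * nr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  cur
}

# Tangential full-width-half-maximum of a reconstructed point target at a
# known center (mm), measured along the direction orthogonal to the radius.
tangential_fwhm <- function(img, center_mm, pitch) {
  n <- nrow(img$values)
  coord <- (seq_len(n) - (n + 1) / 2) * pitch
  ci <- which.min(abs(coord - center_mm[1]))
  cj <- which.min(abs(coord - center_mm[2]))
  # tangential direction for a center on the +x axis is the y direction
  prof <- abs(img$values[ci, ])
  win <- max(1, cj - 30):min(n, cj + 30)
  # equivalent width (area over peak) is robust to bipolar side lobes
  sum(prof[win]) / max(prof[win]) * pitch
}

# Signal envelope via the analytic signal (discrete Hilbert transform).
envelope <- function(v) {
  n <- length(v)
  F <- fft(v)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(fft(F * h, inverse = TRUE) / n)
}

# Arrival-time index (0-based samples) of the envelope peak of an A-line.
arrival_index <- function(v) which.max(envelope(v)) - 1
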