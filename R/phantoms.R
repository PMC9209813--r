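#' Numerical initial-pressure phantoms
#'
#' Three phantom families are used for training-data generation: randomly
#' placed point targets, hollow triangle outlines, and branching vessel
#' trees resembling the cerebral venous sinuses of the rodent brain.  All
#' generators are pure functions of `(grid, parameters, seed)` and place
#' every nonzero pixel inside the centered 40 mm imaging disc.
#'
#' @name phantoms
NULL

new_pressure_map <- function(grid, values) {
  stopifnot(all(dim(values) == c(grid$nx, grid$ny)), all(values >= 0))
  structure(list(grid = grid, values = values), class = "pat_pressure")
}

#' @export
print.pat_pressure <- function(x, ...) {
  cat(sprintf("<pat_pressure> %d x %d px, %d nonzero, max %.3g\n",
              x$grid$nx, x$grid$ny, sum(x$values > 0), max(x$values)))
  invisible(x)
}

#' Point-target phantom
#'
#' Places `n_points` small discs (default diameter 0.5 mm, the size of a
#' pencil-lead cross-section) at random non-overlapping positions inside
#' the imaging disc.  Each disc gets an independent source strength drawn
#' uniformly from `strength_range`.
#'
#' @param grid A [image_grid()].
#' @param n_points Number of point targets (>= 0).
#' @param seed Integer seed; fixed seed gives an identical phantom.
#' @param diameter_mm Disc diameter in mm (at least one pixel).
#' @param strength_range Length-2 range for per-disc source strength.
#' @param margin_mm Keep disc centers this far inside the disc edge.
#' @param max_tries Retry cap for non-overlapping placement.
#' @return A `pat_pressure` map.
#' @export
gen_point_phantom <- function(grid, n_points = 5, seed = NULL,
                              diameter_mm = 0.5,
                              strength_range = c(0.5, 1),
                              margin_mm = 2, max_tries = 1000) {
  stopifnot(n_points >= 0)
  vals <- matrix(0, grid$nx, grid$ny)
  if (n_points == 0) return(new_pressure_map(grid, vals))
  r_px <- max(0.5, diameter_mm / 2 / grid$dx)
  rmax <- grid$fov_mm / 2 - margin_mm - diameter_mm / 2
  with_seed(seed, {
    centers <- matrix(NA_real_, n_points, 2)
    placed <- 0L; tries <- 0L
    while (placed < n_points) {
      if ((tries <- tries + 1L) > max_tries)
        stop("point placement failed: could not place ", n_points,
             " non-overlapping targets in ", max_tries, " attempts")
      ang <- runif(1, 0, 2 * pi)
      rad <- sqrt(runif(1)) * rmax
      cand <- c(rad * cos(ang), rad * sin(ang))
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2
        if (any(d2 < (2.5 * diameter_mm)^2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    strengths <- runif(n_points, strength_range[1], strength_range[2])
    co <- grid_coords(grid)
    for (i in seq_len(n_points)) {
      dx2 <- (co$x - centers[i, 1])^2
      dy2 <- (co$y - centers[i, 2])^2
      disc <- outer(dx2, dy2, `+`) <= (r_px * grid$dx)^2
      vals[disc] <- pmax(vals[disc], strengths[i])
    }
  })
  new_pressure_map(grid, vals)
}

# Rasterize a line segment with a given width (mm) onto the grid.
draw_segment <- function(vals, grid, p1, p2, width_mm, value) {
  co <- grid_coords(grid)
  # bounding box with margin
  pad <- width_mm + 2 * grid$dx
  xi <- which(co$x >= min(p1[1], p2[1]) - pad & co$x <= max(p1[1], p2[1]) + pad)
  yi <- which(co$y >= min(p1[2], p2[2]) - pad & co$y <= max(p1[2], p2[2]) + pad)
  if (!length(xi) || !length(yi)) return(vals)
  X <- matrix(co$x[xi], length(xi), length(yi))
  Y <- matrix(co$y[yi], length(xi), length(yi), byrow = TRUE)
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 == 0) {
    d2 <- (X - p1[1])^2 + (Y - p1[2])^2
  } else {
    t <- pmin(1, pmax(0, ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / L2))
    d2 <- (X - (p1[1] + t * v[1]))^2 + (Y - (p1[2] + t * v[2]))^2
  }
  hit <- d2 <= (width_mm / 2)^2
  sub <- vals[xi, yi]
  sub[hit] <- pmax(sub[hit], value)
  vals[xi, yi] <- sub
  vals
}

# Rasterize an equilateral triangle outline (or filled interior).
draw_triangle <- function(grid, center, side_mm, angle, width_mm,
                          value = 1, filled = FALSE) {
  vals <- matrix(0, grid$nx, grid$ny)
  R <- side_mm / sqrt(3)  # circumradius
  th <- angle + c(0, 2, 4) * pi / 3
  vx <- center[1] + R * cos(th)
  vy <- center[2] + R * sin(th)
  if (filled) {
    co <- grid_coords(grid)
    X <- matrix(co$x, grid$nx, grid$ny)
    Y <- matrix(co$y, grid$nx, grid$ny, byrow = TRUE)
    inside <- rep(TRUE, length(X))
    for (i in 1:3) {
      j <- i %% 3 + 1
      ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
      s <- ex * (Y - vy[i]) - ey * (X - vx[i])
      inside <- inside & (s >= 0)
    }
    vals[matrix(inside, grid$nx, grid$ny)] <- value
  } else {
    for (i in 1:3) {
      j <- i %% 3 + 1
      vals <- draw_segment(vals, grid, c(vx[i], vy[i]), c(vx[j], vy[j]),
                           width_mm, value)
    }
  }
  vals
}

#' Triangle phantom
#'
#' One thin-edged equilateral triangle outline (emulating a horsehair
#' phantom) with random center, rotation, and side length, fully inside the
#' imaging disc.
#'
#' @inheritParams gen_point_phantom
#' @param side_range_mm Side-length bounds in mm.
#' @param line_width_px Edge width in pixels (rasterized as capsules).
#' @param filled Fill the interior instead of drawing the outline.
#' @return A `pat_pressure` map.
#' @export
gen_triangle_phantom <- function(grid, seed = NULL,
                                 side_range_mm = c(10, 25),
                                 line_width_px = 1,
                                 strength_range = c(0.5, 1),
                                 filled = FALSE) {
  Rmax <- side_range_mm[2] / sqrt(3)
  if (Rmax > grid$fov_mm / 2)
    stop("triangle size bounds exceed the imaging disc")
  with_seed(seed, {
    side <- runif(1, side_range_mm[1], side_range_mm[2])
    Rc <- side / sqrt(3)
    cmax <- grid$fov_mm / 2 - Rc - grid$dx
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * max(0, cmax)
    center <- c(rad * cos(ang), rad * sin(ang))
    rot <- runif(1, 0, 2 * pi)
    val <- runif(1, strength_range[1], strength_range[2])
    vals <- draw_triangle(grid, center, side, rot,
                          width_mm = line_width_px * grid$dx,
                          value = val, filled = filled)
  })
  new_pressure_map(grid, vals)
}

#' Vessel phantom
#'
#' A procedural branching structure resembling the sagittal/transverse
#' sinus pattern of the rodent brain: one smooth low-order curved trunk
#' through the disc plus 2-6 lateral branches at random angles, each drawn
#' with an approximately Gaussian cross-section of width 0.3-1.0 mm and an
#' independent magnitude in `strength_range`, with a random global rotation
#' and translation.
#'
#' @inheritParams gen_point_phantom
#' @param n_branch_range Bounds on the number of lateral branches.
#' @param width_range_mm Vessel full-width bounds in mm.
#' @param magnitude_scale Global multiplier on all magnitudes (0 gives an
#'   all-zero map).
#' @return A `pat_pressure` map.
#' @export
gen_vessel_phantom <- function(grid, seed = NULL,
                               n_branch_range = c(2, 6),
                               width_range_mm = c(0.3, 1.0),
                               strength_range = c(0.5, 1),
                               magnitude_scale = 1) {
  stopifnot(magnitude_scale >= 0)
  with_seed(seed, {
    rot <- runif(1, 0, 2 * pi)
    Rot <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    shift <- runif(2, -4, 4)
    rmax <- grid$fov_mm / 2 - 2
    # trunk: low-order polynomial curve spanning the disc
    tt <- seq(-1, 1, length.out = 161)
    a <- runif(1, -6, 6); b <- runif(1, -8, 8)
    trunk <- cbind(tt * (rmax - 2), a * tt^2 + b * tt^3 * 0.3)
    trunk <- t(Rot %*% t(trunk)) + matrix(shift, nrow(trunk), 2, byrow = TRUE)
    vals <- matrix(0, grid$nx, grid$ny)
    wtrunk <- runif(1, max(width_range_mm[1], 0.6), width_range_mm[2])
    vtrunk <- runif(1, strength_range[1], strength_range[2])
    pieces <- list(list(pts = trunk, w = wtrunk, v = vtrunk))
    # lateral branches leaving the trunk
    nb <- sample(seq(n_branch_range[1], n_branch_range[2]), 1)
    for (k in seq_len(nb)) {
      i0 <- sample(20:(nrow(trunk) - 20), 1)
      base <- trunk[i0, ]
      tang <- trunk[i0 + 1, ] - trunk[i0 - 1, ]
      tang <- tang / sqrt(sum(tang^2))
      side <- sample(c(-1, 1), 1)
      ang0 <- atan2(tang[2], tang[1]) + side * runif(1, pi / 5, pi / 2.2)
      len <- runif(1, 5, 14)
      curv <- runif(1, -0.06, 0.06)
      ss <- seq(0, len, by = grid$dx * 2)
      angs <- ang0 + curv * ss
      bp <- cbind(base[1] + cumsum(c(0, diff(ss)) * cos(angs)),
                  base[2] + cumsum(c(0, diff(ss)) * sin(angs)))
      pieces[[length(pieces) + 1]] <-
        list(pts = bp, w = runif(1, width_range_mm[1], width_range_mm[2] * 0.8),
             v = runif(1, strength_range[1], strength_range[2]))
    }
    for (p in pieces) {
      pts <- p$pts
      keep <- pts[, 1]^2 + pts[, 2]^2 <= rmax^2
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) < 2) next
      for (i in seq_len(nrow(pts) - 1))
        vals <- draw_segment(vals, grid, pts[i, ], pts[i + 1, ],
                             p$w, p$v * magnitude_scale)
    }
  })
  vals[!fov_mask(grid)] <- 0
  new_pressure_map(grid, vals)
}

#' Generate a phantom of a named family
#'
#' @param family `"points"`, `"triangle"`, or `"vessel"`.
#' @param grid A [image_grid()].
#' @param seed Integer seed.
#' @param ... Passed on to the family generator.
#' @return A `pat_pressure` map.
#' @export
gen_phantom <- function(family = c("points", "triangle", "vessel"),
                        grid, seed = NULL, ...) {
  family <- match.arg(family)
  switch(family,
         points = gen_point_phantom(grid, seed = seed, ...),
         triangle = gen_triangle_phantom(grid, seed = seed, ...),
         vessel = gen_vessel_phantom(grid, seed = seed, ...))
}
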