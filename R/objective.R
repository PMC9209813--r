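#' Training losses
#'
#' The composite training loss is `L = k1 * L_MAE + k2 * L_FMAE` with
#' defaults `k1 = 1` and `k2 = 0.001`: the pixel-wise mean absolute error
#' is the primary term, and the Fourier mean absolute error (the mean
#' complex modulus of the difference of unnormalized 2D DFTs) adds a small
#' frequency-domain consistency pressure.
#'
#' @param yg Ground-truth image (matrix).
#' @param yp Predicted image (matrix, same shape).
#' @param k1,k2 Loss weights (defaults 1 and 0.001).
#' @return A single non-negative number.
#' @name losses
NULL

check_same_shape <- function(yg, yp) {
  if (!identical(dim(yg), dim(yp)))
    stop("image shapes differ: ", paste(dim(yg), collapse = "x"), " vs ",
         paste(dim(yp), collapse = "x"))
}

#' @rdname losses
#' @export
mae_loss <- function(yg, yp) {
  check_same_shape(yg, yp)
  mean(abs(yg - yp))
}

#' @rdname losses
#' @export
fmae_loss <- function(yg, yp) {
  check_same_shape(yg, yp)
  mean(Mod(fft(yg) - fft(yp)))
}

#' @rdname losses
#' @export
composite_loss <- function(yg, yp, k1 = 1, k2 = 0.001) {
  stopifnot(k1 >= 0, k2 >= 0)
  k1 * mae_loss(yg, yp) + k2 * fmae_loss(yg, yp)
}

# Loss and gradient w.r.t. yp for a [H, W, 1, N] batch (mean over images).
composite_loss_grad <- function(yg, yp, k1 = 1, k2 = 0.001) {
  d <- dim(yp)
  npix <- d[1] * d[2]
  nb <- d[4]
  loss <- 0
  grad <- array(0, d)
  for (n in seq_len(nb)) {
    g <- matrix(yg[, , 1, n], d[1], d[2])
    p <- matrix(yp[, , 1, n], d[1], d[2])
    diff <- p - g
    loss <- loss + k1 * mean(abs(diff))
    gi <- k1 * sign(diff) / npix
    if (k2 > 0) {
      D <- fft(p) - fft(g)
      m <- Mod(D)
      loss <- loss + k2 * mean(m)
      u <- D
      nzm <- m > 0
      u[nzm] <- u[nzm] / m[nzm]
      u[!nzm] <- 0
      gi <- gi + k2 * Re(fft(u, inverse = TRUE)) / npix
    }
    grad[, , 1, n] <- gi
  }
  list(loss = loss / nb, grad = grad / nb)
}

# --- evaluation metrics ----------------------------------------------------

#' Peak signal-to-noise ratio
#'
#' Data range fixed to 1 (images are min-max normalized); identical images
#' are reported at a 100 dB cap rather than infinity.
#'
#' @param yg,yp Images of equal shape.
#' @param cap Maximum reported value in dB.
#' @return PSNR in dB.
#' @export
psnr <- function(yg, yp, cap = 100) {
  check_same_shape(yg, yp)
  mse <- mean((yg - yp)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(1 / mse))
}

#' Structural similarity index
#'
#' Standard single-scale SSIM with a uniform 7 x 7 window, data range 1,
#' and the usual stabilization constants `C1 = (0.01)^2`, `C2 = (0.03)^2`;
#' local statistics are computed on the valid (fully overlapping) region.
#'
#' @param yg,yp Images of equal shape.
#' @param win Window side length (odd).
#' @return Mean SSIM over the image.
#' @export
ssim_index <- function(yg, yp, win = 7) {
  check_same_shape(yg, yp)
  C1 <- 0.01^2; C2 <- 0.03^2
  box <- function(m) {
    k <- array(1 / win^2, c(win, win, 1, 1))
    a <- array(m, c(dim(m), 1, 1))
    cpp_conv2d_fwd(a, k, 1L, 1L, 0L)[, , 1, 1]
  }
  mx <- box(yg); my <- box(yp)
  sxx <- box(yg^2) - mx^2
  syy <- box(yp^2) - my^2
  sxy <- box(yg * yp) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

#' Pixelwise Pearson correlation
#'
#' @param yg,yp Images of equal shape; `NA` if either is constant.
#' @return Correlation coefficient in [-1, 1] (or `NA`).
#' @export
pcc <- function(yg, yp) {
  check_same_shape(yg, yp)
  if (sd(yg) == 0 || sd(yp) == 0) return(NA_real_)
  cor(as.vector(yg), as.vector(yp))
}

#' Evaluate a set of image pairs
#'
#' Computes per-image PCC, SSIM, PSNR and MAE for paired ground-truth and
#' predicted images (both normalized to [0, 1]) and summarizes each metric
#' as mean and standard deviation.  Images with undefined correlation
#' (constant) are excluded from the PCC summary with a warning count.
#'
#' @param yg_set,yp_set `[H, W, n]` arrays (or lists of matrices).
#' @return A `pat_metrics` object: data frame `summary` (metric, mean, sd)
#'   and the per-image values.
#' @export
evaluate_pairs <- function(yg_set, yp_set) {
  as_stack <- function(a) {
    if (is.list(a)) a <- simplify2array(a)
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
    a
  }
  yg_set <- as_stack(yg_set); yp_set <- as_stack(yp_set)
  stopifnot(identical(dim(yg_set), dim(yp_set)))
  n <- dim(yg_set)[3]
  per <- data.frame(pcc = numeric(n), ssim = numeric(n),
                    psnr = numeric(n), mae = numeric(n))
  for (i in seq_len(n)) {
    g <- yg_set[, , i]; p <- yp_set[, , i]
    per$pcc[i] <- pcc(g, p)
    per$ssim[i] <- ssim_index(g, p)
    per$psnr[i] <- psnr(g, p)
    per$mae[i] <- mae_loss(g, p)
  }
  n_undef <- sum(is.na(per$pcc))
  if (n_undef > 0)
    warning(n_undef, " image pair(s) had undefined PCC (constant image); ",
            "excluded from the PCC summary")
  summ <- data.frame(
    metric = c("pcc", "psnr", "ssim", "mae"),
    mean = c(mean(per$pcc, na.rm = TRUE), mean(per$psnr),
             mean(per$ssim), mean(per$mae)),
    sd = c(sd(per$pcc, na.rm = TRUE), sd(per$psnr),
           sd(per$ssim), sd(per$mae)))
  structure(list(summary = summ, per_image = per, n_undefined_pcc = n_undef,
                 psnr_convention = "data_range_1"),
            class = "pat_metrics")
}

#' @export
print.pat_metrics <- function(x, ...) {
  s <- x$summary
  cat("<pat_metrics>\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %7.4f ± %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
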