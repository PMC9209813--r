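# Minimal reverse-mode engine for the image-to-image networks.  Tensors are
# R arrays [H, W, C, N]; a tape of nodes is built per forward pass and
# walked backwards to accumulate parameter gradients.  Convolutions run
# through the im2col/GEMM kernels in src/.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e
}

ag_node <- function(tape, value, bk = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$bk <- bk
  tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

ag_accum <- function(target, g) {
  if (is.null(target$g)) target$g <- g else target$g <- target$g + g
  invisible(NULL)
}

ag_backward <- function(tape, out, gout) {
  out$g <- gout
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$bk) && !is.null(n$g)) n$bk(n)
    n$bk <- NULL
  }
  invisible(NULL)
}

# Parameter: environment with value, gradient, and Adam state.
new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- NULL
  p$m <- NULL
  p$s <- NULL
  p
}

# --- ops ------------------------------------------------------------------

ag_input <- function(tape, x) ag_node(tape, x)

ag_conv <- function(tape, x, W, stride = 1L, dil = 1L, pad = 1L,
                    bias = NULL) {
  y <- cpp_conv2d_fwd(x$v, W$v, stride, dil, pad)
  if (!is.null(bias)) {
    d <- dim(y)
    y <- y + rep(bias$v, each = d[1] * d[2])
  }
  ag_node(tape, y, bk = function(n) {
    dy <- n$g
    if (!is.null(bias)) {
      d <- dim(dy)
      db <- colSums(matrix(aperm(dy, c(1, 2, 4, 3)),
                           d[1] * d[2] * d[4], d[3]))
      ag_accum(bias, db)
    }
    ag_accum(W, cpp_conv2d_bwd_filter(x$v, dy, dim(W$v), stride, dil, pad))
    ag_accum(x, cpp_conv2d_bwd_data(dy, W$v, dim(x$v), stride, dil, pad))
  })
}

# Transposed convolution (stride-2 upsampling): forward is the data-gradient
# of a stride-2 conv, backward swaps the roles.  W is [kh, kw, Cout, Cin]
# in the underlying conv's orientation.
ag_conv_transpose <- function(tape, x, W, out_hw, stride = 2L, pad = 1L) {
  d <- dim(x$v)
  xdim <- c(out_hw[1], out_hw[2], dim(W$v)[3], d[4])
  y <- cpp_conv2d_bwd_data(x$v, W$v, xdim, stride, 1L, pad)
  ag_node(tape, y, bk = function(n) {
    dy <- n$g
    ag_accum(W, cpp_conv2d_bwd_filter(dy, x$v, dim(W$v), stride, 1L, pad))
    ag_accum(x, cpp_conv2d_fwd(dy, W$v, stride, 1L, pad))
  })
}

bn_batch_stats <- function(x, state, training, momentum, eps) {
  if (training) {
    d <- dim(x)
    M <- d[1] * d[2] * d[4]
    st <- cpp_bn_stats(x)
    state$mean <- (1 - momentum) * state$mean + momentum * st$mean
    state$var <- (1 - momentum) * state$var +
      momentum * st$var * M / max(1, M - 1)
    list(mu = st$mean, istd = 1 / sqrt(st$var + eps))
  } else {
    list(mu = state$mean, istd = 1 / sqrt(state$var + eps))
  }
}

# Batch normalization over (H, W, N) per channel.
ag_batchnorm <- function(tape, x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  s <- bn_batch_stats(x$v, state, training, momentum, eps)
  y <- cpp_bn_fwd(x$v, s$mu, s$istd, gamma$v, beta$v)
  ag_node(tape, y, bk = function(n) {
    b <- cpp_bn_bwd(n$g, x$v, s$mu, s$istd, gamma$v, training)
    ag_accum(gamma, b$dgamma)
    ag_accum(beta, b$dbeta)
    ag_accum(x, b$dx)
  })
}

# Fused batch-norm + ReLU (the standard convolution-block tail).
ag_bn_relu <- function(tape, x, gamma, beta, state, training = TRUE,
                       momentum = 0.1, eps = 1e-5) {
  s <- bn_batch_stats(x$v, state, training, momentum, eps)
  y <- cpp_bn_relu_fwd(x$v, s$mu, s$istd, gamma$v, beta$v)
  ag_node(tape, y, bk = function(n) {
    b <- cpp_bn_relu_bwd(n$g, y, x$v, s$mu, s$istd, gamma$v, training)
    ag_accum(gamma, b$dgamma)
    ag_accum(beta, b$dbeta)
    ag_accum(x, b$dx)
  })
}

ag_relu <- function(tape, x) {
  y <- cpp_relu_fwd(x$v)
  ag_node(tape, y, bk = function(n) {
    ag_accum(x, cpp_relu_bwd(n$g, y))
  })
}

ag_concat <- function(tape, xs) {
  y <- cpp_concat_ch(lapply(xs, function(n) n$v))
  ag_node(tape, y, bk = function(n) {
    at <- 0L
    for (xn in xs) {
      cc <- dim(xn$v)[3]
      ag_accum(xn, cpp_slice_ch(n$g, at, cc))
      at <- at + cc
    }
  })
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$v + b$v, bk = function(n) {
    ag_accum(a, n$g)
    ag_accum(b, n$g)
  })
}

# --- optimizer ------------------------------------------------------------

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) { p$m <- p$g * 0; p$s <- p$g * 0 }
    cpp_adam_update(p$v, p$g, p$m, p$s, lr, t, beta1, beta2, eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}
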