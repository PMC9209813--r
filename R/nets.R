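#' Network configuration
#'
#' Hyper-structure shared by the four image-to-image architectures.  At
#' level `l` the target feature count is `fl = 2^(l-1) * fi` and the dense
#' growth rate is `kl = 2^(l-1) * growth_base`; a dense block runs
#' `fi / growth_base` steps so its channel count grows by exactly `fl`.
#' Dilated dense steps split `kl` into equal halves of dilation rate 1 and
#' 2 (the rate is capped at 2 to limit gridding artifacts); the `"dd"`
#' baseline instead stacks rates 1, 2 and 4 at full `kl` each, which is
#' what makes it parameter-hungry.
#'
#' @param variant `"hd"` (dilated dense encoder, standard dense decoder,
#'   residual bridge), `"fd"` (standard dense both paths), `"dd"`
#'   (multi-rate dilated dense both paths), or `"unet"` (plain double-conv
#'   blocks).
#' @param fi Initial feature count; must be divisible by `growth_base`.
#' @param levels Number of resolution levels (default 4: three down/up
#'   transitions, 16 x 16 bottleneck for 128 x 128 inputs).
#' @param growth_base Base growth rate (8).
#' @param max_dilation Dilation cap for the hybrid dilated split.
#' @param strict_shape Require 128 x 128 inputs when `TRUE`.
#' @return A `net_config` object with derived per-level `fl` and `kl`.
#' @examples
#' cfg <- net_config("hd", fi = 32)
#' cfg$fl  # 32 64 128 256
#' cfg$kl  # 8 16 32 64
#' @export
net_config <- function(variant = c("hd", "fd", "dd", "unet"), fi = 32,
                       levels = 4, growth_base = 8, max_dilation = 2,
                       strict_shape = FALSE) {
  variant <- match.arg(variant)
  stopifnot(fi >= growth_base, fi %% growth_base == 0, levels >= 2)
  l <- seq_len(levels)
  structure(list(variant = variant, fi = as.integer(fi),
                 levels = as.integer(levels),
                 growth_base = as.integer(growth_base),
                 max_dilation = as.integer(max_dilation),
                 strict_shape = strict_shape,
                 fl = as.integer(2^(l - 1) * fi),
                 kl = as.integer(2^(l - 1) * growth_base),
                 steps = as.integer(fi / growth_base)),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("<net_config> %s, fi=%d, levels=%d, fl=[%s], kl=[%s]\n",
              x$variant, x$fi, x$levels,
              paste(x$fl, collapse = ","), paste(x$kl, collapse = ",")))
  invisible(x)
}

# Dilation rates used by one dense step of a given variant/path.
step_dilations <- function(cfg, mode) {
  switch(mode,
         standard = 1L,
         dilated = c(1L, min(2L, cfg$max_dilation)),
         multirate = c(1L, 2L, 4L))
}

# --- module constructors ---------------------------------------------------
# Each module is a list(params = <param envs>, fwd = function(tape, x,
# training) -> node).  `reg` collects every parameter for the optimizer.

reg_add <- function(reg, name, p) {
  reg$params[[name]] <- p
  p
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

mod_conv_block <- function(reg, name, cin, cout, k = 3, stride = 1,
                           dil = 1, bn = TRUE, act = TRUE, bias = !bn) {
  pad <- as.integer(dil * (k - 1) / 2)
  W <- reg_add(reg, paste0(name, ".W"), new_param(he_init(k, k, cin, cout)))
  b <- if (bias) reg_add(reg, paste0(name, ".b"), new_param(numeric(cout)))
  if (bn) {
    gamma <- reg_add(reg, paste0(name, ".gamma"), new_param(rep(1, cout)))
    beta <- reg_add(reg, paste0(name, ".beta"), new_param(numeric(cout)))
    st <- new.env(parent = emptyenv())
    st$mean <- numeric(cout); st$var <- rep(1, cout)
    reg$state[[name]] <- st
  }
  list(cout = cout, fwd = function(tape, x, training) {
    h <- ag_conv(tape, x, W, stride = as.integer(stride),
                 dil = as.integer(dil), pad = pad, bias = b)
    if (bn && act) {
      h <- ag_bn_relu(tape, h, gamma, beta, reg$state[[name]],
                      training = training)
    } else {
      if (bn) h <- ag_batchnorm(tape, h, gamma, beta, reg$state[[name]],
                                training = training)
      if (act) h <- ag_relu(tape, h)
    }
    h
  })
}

# Dense block: `steps` iterations, each consuming the concatenation of all
# previous features and emitting `kl` new channels (split across the
# mode's dilation rates).  Optional 1 x 1 entry projection.
mod_dense_block <- function(reg, name, cin, level, cfg, mode,
                            entry_to = NULL) {
  mods <- list()
  cur <- cin
  if (!is.null(entry_to)) {
    mods$entry <- mod_conv_block(reg, paste0(name, ".entry"), cin,
                                 entry_to, k = 1)
    cur <- entry_to
  }
  k <- cfg$kl[level]
  dils <- step_dilations(cfg, mode)
  per <- as.integer(k / length(dils))
  if (mode == "multirate") per <- k
  steps <- vector("list", cfg$steps)
  for (s in seq_len(cfg$steps)) {
    branches <- lapply(seq_along(dils), function(j) {
      mod_conv_block(reg, sprintf("%s.s%d.d%d", name, s, dils[j]),
                     cur, per, k = 3, dil = dils[j])
    })
    steps[[s]] <- branches
    cur <- cur + per * length(dils)
  }
  list(cout = cur, fwd = function(tape, x, training) {
    if (!is.null(mods$entry)) x <- mods$entry$fwd(tape, x, training)
    feats <- list(x)
    for (s in seq_len(cfg$steps)) {
      inp <- if (length(feats) == 1) feats[[1]] else ag_concat(tape, feats)
      new <- lapply(steps[[s]], function(br) br$fwd(tape, inp, training))
      feats[[length(feats) + 1]] <-
        if (length(new) == 1) new[[1]] else ag_concat(tape, new)
    }
    ag_concat(tape, feats)
  })
}

mod_double_conv <- function(reg, name, cin, cmid, cout) {
  b1 <- mod_conv_block(reg, paste0(name, ".c1"), cin, cmid)
  b2 <- mod_conv_block(reg, paste0(name, ".c2"), cmid, cout)
  list(cout = cout, fwd = function(tape, x, training)
    b2$fwd(tape, b1$fwd(tape, x, training), training))
}

mod_residual_bridge <- function(reg, name, cin) {
  b1 <- mod_conv_block(reg, paste0(name, ".c1"), cin, cin)
  b2 <- mod_conv_block(reg, paste0(name, ".c2"), cin, cin)
  list(cout = cin, fwd = function(tape, x, training) {
    h <- b2$fwd(tape, b1$fwd(tape, x, training), training)
    ag_add(tape, h, x)
  })
}

# Level block of the variant, returning the module and its output width.
mod_level_block <- function(reg, name, cin, level, cfg, path) {
  v <- cfg$variant
  f <- cfg$fl[level]
  if (v == "unet") {
    if (path == "enc") mod_double_conv(reg, name, cin, 2 * f, 2 * f)
    else mod_double_conv(reg, name, cin, f, 2 * f)
  } else {
    mode <- if (v == "dd") "multirate"
            else if (v == "hd" && path == "enc") "dilated"
            else "standard"
    entry <- if (path == "dec") f else NULL
    mod_dense_block(reg, name, cin, level, cfg, mode, entry_to = entry)
  }
}

#' Build an image-to-image network
#'
#' Constructs the HD-UNet or one of the comparison architectures as a
#' callable network mapping a 1-channel image to a 1-channel image of the
#' same size.  Downsampling is a 1 x 1 convolution block followed by a
#' stride-2 3 x 3 convolution block; upsampling is a transposed stride-2
#' 3 x 3 convolution; skip connections concatenate the encoder level input
#' at every level; the head is two 3 x 3 convolution blocks ending in a
#' single-channel ReLU output (targets are normalized to [0, 1]).  Every
#' convolution block is convolution, batch normalization, then ReLU.
#'
#' @param config A [net_config()].
#' @param seed Seed for the variance-preserving (He) weight initialization.
#' @return A `pat_net` with elements `config`, `params`, and forward
#'   machinery; apply it with [net_forward()].
#' @export
build_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "net_config"))
  reg <- new.env(parent = emptyenv())
  reg$params <- list(); reg$state <- list()
  L <- config$levels
  with_seed(seed, {
    stem <- mod_conv_block(reg, "stem", 1, config$fi)
    enc <- vector("list", L); down1 <- vector("list", L - 1)
    down2 <- vector("list", L - 1)
    cin <- config$fi
    enc_in_ch <- integer(L)
    for (l in seq_len(L)) {
      enc_in_ch[l] <- cin
      enc[[l]] <- mod_level_block(reg, sprintf("enc%d", l), cin, l,
                                  config, "enc")
      if (l < L) {
        fnext <- config$fl[l + 1]
        down1[[l]] <- mod_conv_block(reg, sprintf("down%d.proj", l),
                                     enc[[l]]$cout, fnext, k = 1)
        down2[[l]] <- mod_conv_block(reg, sprintf("down%d.pool", l),
                                     fnext, fnext, k = 3, stride = 2)
        cin <- fnext
      }
    }
    bridge <- if (config$variant == "hd")
      mod_residual_bridge(reg, "bridge", enc[[L]]$cout) else NULL
    cur <- enc[[L]]$cout
    up <- vector("list", L - 1); dec <- vector("list", L - 1)
    for (l in rev(seq_len(L - 1))) {
      f <- config$fl[l]
      Wup <- reg_add(reg, sprintf("up%d.W", l),
                     new_param(he_init(3, 3, f, cur)))
      up[[l]] <- list(W = Wup, cin = cur, cout = f)
      dec[[l]] <- mod_level_block(reg, sprintf("dec%d", l),
                                  f + enc_in_ch[l], l, config, "dec")
      cur <- dec[[l]]$cout
    }
    head1 <- mod_conv_block(reg, "head1", cur, config$fi)
    headW <- reg_add(reg, "head2.W", new_param(he_init(3, 3, config$fi, 1)))
    headb <- reg_add(reg, "head2.b", new_param(numeric(1)))
  })
  graph <- function(x, training = FALSE) {
    tape <- ag_tape()
    inp <- ag_input(tape, x)
    h <- stem$fwd(tape, inp, training)
    skips <- vector("list", L)
    for (l in seq_len(L)) {
      skips[[l]] <- h
      h <- enc[[l]]$fwd(tape, h, training)
      if (l < L) {
        h <- down1[[l]]$fwd(tape, h, training)
        h <- down2[[l]]$fwd(tape, h, training)
      }
    }
    if (!is.null(bridge)) h <- bridge$fwd(tape, h, training)
    for (l in rev(seq_len(L - 1))) {
      out_hw <- dim(skips[[l]]$v)[1:2]
      h <- ag_conv_transpose(tape, h, up[[l]]$W, out_hw)
      h <- ag_concat(tape, list(h, skips[[l]]))
      h <- dec[[l]]$fwd(tape, h, training)
    }
    h <- head1$fwd(tape, h, training)
    h <- ag_conv(tape, h, headW, bias = headb)
    h <- ag_relu(tape, h)
    list(out = h, input = inp, tape = tape)
  }
  structure(list(config = config, params = reg$params, state = reg$state,
                 graph = graph, seed = seed),
            class = "pat_net")
}

#' @export
print.pat_net <- function(x, ...) {
  cat(sprintf("<pat_net> %s (fi=%d), %d parameters\n",
              x$config$variant, x$config$fi, count_parameters(x)))
  invisible(x)
}

# Coerce an image / stack to the engine's [H, W, 1, N] layout.
as_batch <- function(x) {
  if (inherits(x, "pat_image")) x <- x$values
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2) dim(x) <- c(d, 1, 1)
  else if (length(d) == 3) x <- array(x, c(d[1], d[2], 1, d[3]))
  x
}

#' Apply a network to images
#'
#' @param net A `pat_net` from [build_network()].
#' @param x A matrix (one image), `[H, W, n]` array (a stack), or
#'   `[H, W, 1, n]` array.
#' @param training Use batch statistics and record the tape (internal use);
#'   the default applies the network in inference mode.
#' @return Output with the same shape as the input.
#' @export
net_forward <- function(net, x, training = FALSE) {
  din <- dim(x %||% NULL)
  if (inherits(x, "pat_image")) din <- dim(x$values)
  xb <- as_batch(x)
  cfg <- net$config
  if (cfg$strict_shape && !all(dim(xb)[1:2] == c(128, 128)))
    stop("network built with strict_shape requires 128 x 128 input")
  if (any(dim(xb)[1:2] %% 2^(cfg$levels - 1) != 0))
    stop("input size must be divisible by ", 2^(cfg$levels - 1))
  y <- net$graph(xb, training = training)$out$v
  if (length(din) == 2) dim(y) <- din
  else if (length(din) == 3) dim(y) <- din
  y
}

#' Count trainable parameters
#'
#' Batch-normalization running statistics are not counted; scale/shift
#' parameters are.
#'
#' @param net A `pat_net`.
#' @return Integer total of trainable scalars.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, function(p) length(p$v), numeric(1)))
}

#' Analytic receptive field at the bottleneck
#'
#' Composes kernel extents, dilations and strides along the encoder path
#' (through the deepest dense block) to give the receptive field, in input
#' pixels, of one bottleneck unit.  Used to quantify how the dilated split
#' enlarges context without extra parameters.
#'
#' @param config A [net_config()].
#' @return Receptive field side length in pixels.
#' @export
receptive_field <- function(config) {
  rf <- 1; jump <- 1
  grow <- function(k, dil) rf <<- rf + (k - 1) * dil * jump
  grow(3, 1)  # stem
  mode_for <- function() switch(config$variant,
                                hd = "dilated", dd = "multirate",
                                fd = "standard", unet = "standard")
  for (l in seq_len(config$levels)) {
    dils <- if (config$variant == "unet") c(1, 1)
            else rep(max(step_dilations(config, mode_for())), config$steps)
    for (d in dils) grow(3, d)
    if (l < config$levels) {
      grow(3, 1)       # stride-2 conv
      jump <- jump * 2
    }
  }
  rf
}

#' Standalone dense block (for inspection and testing)
#'
#' Builds one dense block exactly as used inside the networks and returns
#' it as a tiny network whose forward pass exposes the channel ledger.
#'
#' @param in_channels Input channel count.
#' @param level Level `l` (sets the growth rate `kl`).
#' @param config A [net_config()].
#' @param mode `"standard"`, `"dilated"`, or `"multirate"`.
#' @param entry_to Optional 1 x 1 entry projection width.
#' @param seed Initialization seed.
#' @return List with `cout` (output channels) and `forward(x)`.
#' @export
dense_block <- function(in_channels, level, config, mode = "standard",
                        entry_to = NULL, seed = 1) {
  reg <- new.env(parent = emptyenv())
  reg$params <- list(); reg$state <- list()
  m <- with_seed(seed,
    mod_dense_block(reg, "blk", in_channels, level, config, mode,
                    entry_to = entry_to))
  list(cout = m$cout, params = reg$params,
       forward = function(x, training = FALSE) {
         tape <- ag_tape()
         m$fwd(tape, ag_input(tape, x), training)$v
       })
}
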