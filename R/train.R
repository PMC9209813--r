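#' Training configuration
#'
#' Defaults follow the stock protocol: Adam with initial learning rate
#' 0.001, halved (factor 0.5) after `lr_patience` epochs without
#' improvement in validation composite loss, 100 epochs, batch size 2,
#' 90:5:5 train/validation/test split, and 10 resplit repeats for
#' cross-validation.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_factor Multiplicative learning-rate reduction factor.
#' @param lr_patience Epochs without validation improvement before the
#'   learning rate is reduced.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param split Train/validation/test percentages (must sum to 100).
#' @param k_repeats Number of random resplits for cross-validation.
#' @param min_lr Learning-rate floor.
#' @param k1,k2 Composite-loss weights.
#' @param seed Base seed for shuffling and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 0.001, lr_factor = 0.5,
                         lr_patience = 5, epochs = 100, batch_size = 2,
                         split = c(90, 5, 5), k_repeats = 10,
                         min_lr = 1e-6, k1 = 1, k2 = 0.001, seed = 1) {
  stopifnot(batch_size >= 1, epochs >= 1, sum(split) == 100)
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = lr_patience, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 k_repeats = as.integer(k_repeats), min_lr = min_lr,
                 k1 = k1, k2 = k2, seed = seed),
            class = "train_config")
}

#' Random train/validation/test split
#'
#' Disjoint index sets covering `1..n` with sizes `round(0.90 n)`,
#' `round(0.05 n)` and the remainder (for the default 90:5:5 ratios).
#'
#' @param n Dataset size (>= 20).
#' @param ratios Percentages summing to 100.
#' @param seed Integer seed; the split is deterministic per seed.
#' @return List of integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, ratios = c(90, 5, 5), seed = 1) {
  stopifnot(n >= 20)
  if (sum(ratios) != 100) stop("split ratios must sum to 100")
  perm <- with_seed(seed, sample.int(n))
  n_train <- round(ratios[1] / 100 * n)
  n_val <- round(ratios[2] / 100 * n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1):n]))
}

# Reduce-on-plateau learning-rate schedule.  Returns a stateful stepper:
# feed it the validation loss each epoch, read $lr.
plateau_scheduler <- function(initial_lr, factor = 0.5, patience = 5,
                              min_lr = 1e-6) {
  e <- new.env(parent = emptyenv())
  e$lr <- initial_lr
  e$best <- Inf
  e$wait <- 0L
  e$step <- function(val_loss) {
    if (val_loss < e$best) {
      e$best <- val_loss
      e$wait <- 0L
    } else {
      e$wait <- e$wait + 1L
      if (e$wait >= patience) {
        e$lr <- max(min_lr, e$lr * factor)
        e$wait <- 0L
      }
    }
    e$lr
  }
  e
}

dataset_slice <- function(data, idx) {
  list(X = data$X[, , idx, drop = FALSE], Y = data$Y[, , idx, drop = FALSE])
}

batch_loss_eval <- function(net, X, Y, k1, k2, batch = 8) {
  n <- dim(X)[3]
  tot <- 0
  for (i0 in seq(1, n, by = batch)) {
    idx <- i0:min(n, i0 + batch - 1)
    xb <- as_batch(X[, , idx, drop = FALSE])
    yb <- as_batch(Y[, , idx, drop = FALSE])
    out <- net$graph(xb, training = FALSE)$out$v
    tot <- tot + composite_loss_grad(yb, out, k1, k2)$loss * length(idx)
  }
  tot / n
}

#' Train a network
#'
#' Adam optimization of the composite loss over (input, ground truth)
#' image pairs, with per-epoch validation monitoring and
#' reduce-on-plateau learning-rate scheduling.  Fully deterministic for a
#' fixed configuration seed.
#'
#' @param net A `pat_net` from [build_network()].
#' @param data A `pat_dataset` (or list with `[H, W, n]` arrays `X`, `Y`).
#' @param config A [train_config()].
#' @param val Optional validation set of the same form; when omitted the
#'   training set is monitored.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `net` and a `history` data frame
#'   (epoch, train/val composite loss, learning rate).
#' @export
train_network <- function(net, data, config = train_config(), val = NULL,
                          verbose = FALSE) {
  n <- dim(data$X)[3]
  if (n < 1) stop("empty training set")
  if (is.null(val)) val <- data
  sched <- plateau_scheduler(config$initial_lr, config$lr_factor,
                             config$lr_patience, config$min_lr)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  t_adam <- 0L
  lr <- config$initial_lr
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed * 10000 + ep, sample.int(n))
    ep_loss <- 0; nb <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(n, i0 + config$batch_size - 1)]
      xb <- as_batch(data$X[, , idx, drop = FALSE])
      yb <- as_batch(data$Y[, , idx, drop = FALSE])
      g <- net$graph(xb, training = TRUE)
      lg <- composite_loss_grad(yb, g$out$v, config$k1, config$k2)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", ep,
             "; reduce the learning rate")
      zero_grads(net$params)
      ag_backward(g$tape, g$out, lg$grad)
      t_adam <- t_adam + 1L
      adam_step(net$params, lr, t_adam)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    vl <- batch_loss_eval(net, val$X, val$Y, config$k1, config$k2)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / nb,
                                val_loss = vl, lr = lr))
    lr <- sched$step(vl)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      ep, ep_loss / nb, vl, lr))
  }
  list(net = net, history = history)
}

#' Predict with a trained network
#'
#' @param net A trained `pat_net`.
#' @param X `[H, W, n]` array of input images.
#' @param batch Images per forward pass.
#' @return `[H, W, n]` array of restored images.
#' @export
net_predict <- function(net, X, batch = 8) {
  d <- dim(X)
  if (length(d) == 2) dim(X) <- c(d, 1)
  n <- dim(X)[3]
  out <- array(0, dim(X))
  for (i0 in seq(1, n, by = batch)) {
    idx <- i0:min(n, i0 + batch - 1)
    out[, , idx] <- net_forward(net, X[, , idx, drop = FALSE])
  }
  if (length(d) == 2) dim(out) <- d
  out
}

#' Repeated cross-validation over architectures
#'
#' For each of `k_repeats` random 90:5:5 resplits: a fresh network per
#' variant is trained on the training portion and evaluated on that
#' repeat's held-out test portion; metrics are aggregated as mean and
#' standard deviation per variant.
#'
#' @param data A `pat_dataset`.
#' @param variants Character vector of architecture variants.
#' @param config A [train_config()] (its `k_repeats` sets the resplits).
#' @param fi Initial feature count for every variant.
#' @param verbose Print progress.
#' @return A `pat_cv` object: `table` has one row per variant with
#'   mean ± sd for PCC, PSNR, SSIM and MAE across all repeats' test images.
#' @export
cross_validate <- function(data, variants = c("hd", "fd", "dd", "unet"),
                           config = train_config(), fi = 32,
                           verbose = FALSE) {
  if (config$k_repeats < 2) stop("k_repeats must be >= 2 for sd estimates")
  n <- dim(data$X)[3]
  per <- list()
  for (r in seq_len(config$k_repeats)) {
    sp <- split_dataset(n, config$split, seed = config$seed * 1000 + r)
    stopifnot(length(intersect(sp$train, sp$test)) == 0)
    tr <- dataset_slice(data, sp$train)
    va <- dataset_slice(data, sp$val)
    te <- dataset_slice(data, sp$test)
    for (v in variants) {
      if (verbose) message("repeat ", r, ", variant ", v)
      net <- build_network(net_config(v, fi = fi),
                           seed = config$seed * 100 + r)
      fit <- train_network(net, tr, config, val = va)
      pred <- net_predict(fit$net, te$X)
      m <- evaluate_pairs(te$Y, pred)
      per[[length(per) + 1]] <- cbind(variant = v, repeat_id = r,
                                      m$per_image)
    }
  }
  per <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(per, per$variant), function(d) {
    data.frame(variant = d$variant[1],
               pcc_mean = mean(d$pcc, na.rm = TRUE),
               pcc_sd = sd(d$pcc, na.rm = TRUE),
               psnr_mean = mean(d$psnr), psnr_sd = sd(d$psnr),
               ssim_mean = mean(d$ssim), ssim_sd = sd(d$ssim),
               mae_mean = mean(d$mae), mae_sd = sd(d$mae))
  }))
  agg <- agg[match(variants, agg$variant), ]
  rownames(agg) <- NULL
  structure(list(table = agg, per_image = per,
                 k_repeats = config$k_repeats),
            class = "pat_cv")
}

#' @export
print.pat_cv <- function(x, ...) {
  cat(sprintf("<pat_cv> %d resplit repeats\n", x$k_repeats))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-5s PCC %.2f±%.2f  PSNR %.2f±%.2f  SSIM %.2f±%.2f  MAE %.3f±%.3f\n",
                t$variant[i], t$pcc_mean[i], t$pcc_sd[i], t$psnr_mean[i],
                t$psnr_sd[i], t$ssim_mean[i], t$ssim_sd[i],
                t$mae_mean[i], t$mae_sd[i]))
  invisible(x)
}
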