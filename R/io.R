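#' Save / load a paired dataset
#'
#' Datasets are stored as a self-describing serialized container holding
#' the `X`/`Y` image arrays in 64-bit precision together with preset
#' metadata, per-pair generation parameters and seeds, and a schema
#' version; loading validates the schema and round-trips bit-identically.
#'
#' @param dataset A `pat_dataset` from [build_dataset()].
#' @param path Output file path.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   restored `pat_dataset`.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pat_dataset"))
  saveRDS(unclass(dataset), path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  obj <- readRDS(path)
  need <- c("X", "Y", "meta", "preset", "seed", "schema")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("dataset container is missing required group(s): ",
         paste(missing, collapse = ", "))
  if (obj$schema != 1L)
    stop("unsupported dataset schema version: ", obj$schema)
  if (!identical(dim(obj$X), dim(obj$Y)))
    stop("corrupted container: X and Y shapes differ")
  class(obj) <- "pat_dataset"
  obj
}

#' Export an image as PNG (for inspection)
#'
#' @param image A `pat_image`, matrix, or `pat_pressure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  v <- if (inherits(image, "pat_image") || inherits(image, "pat_pressure"))
    image$values else image
  rng <- range(v)
  if (rng[1] == rng[2]) v <- v * 0 else v <- (v - rng[1]) / diff(rng)
  png::writePNG(t(v)[nrow(t(v)):1, , drop = FALSE], path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A validated, file-round-trippable bundle of the knobs of an end-to-end
#' run (phantom generation, simulation, reconstruction, training,
#' evaluation).  Unknown keys are rejected.
#'
#' @param preset `"1ust"` or `"8ust"`.
#' @param n_phantoms Number of training pairs to simulate.
#' @param variants Architectures to train and compare.
#' @param fi Initial feature count.
#' @param epochs,batch_size,k_repeats Training-protocol settings.
#' @param gt_positions Optional override of the ground-truth detector
#'   count.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "1ust", n_phantoms = 100,
                       variants = "hd", fi = 16, epochs = 10,
                       batch_size = 2, k_repeats = 1,
                       gt_positions = NULL, seed = 1,
                       out_dir = tempfile("patkit_run_")) {
  cfg <- list(preset = preset, n_phantoms = as.integer(n_phantoms),
              variants = variants, fi = as.integer(fi),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              k_repeats = as.integer(k_repeats),
              gt_positions = gt_positions, seed = as.integer(seed),
              out_dir = out_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("preset", "n_phantoms", "variants", "fi", "epochs",
               "batch_size", "k_repeats", "gt_positions", "seed",
               "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stopifnot(cfg$preset %in% c("1ust", "8ust"),
            cfg$n_phantoms >= 1, cfg$fi >= 8, cfg$epochs >= 1,
            all(cfg$variants %in% c("hd", "fd", "dd", "unet")))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' YAML round-trip of a [run_config()]; unknown keys are rejected on read.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the end-to-end experiment
#'
#' One call reproduces a (typically desk-scale) version of the full
#' workflow: generate phantoms, simulate sparse and dense scans,
#' reconstruct image pairs, train the requested architectures, and emit a
#' cross-validation-style metrics table plus side-by-side
#' sparse-input / network / ground-truth image panels.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return List with the dataset path, trained networks, the metrics
#'   table, baseline (input vs ground truth) metrics, and the parameter
#'   echo with per-stage seeds.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[patkit] ", ...)
  say("stage 1/3: simulating ", cfg$n_phantoms, " pairs (", cfg$preset, ")")
  data <- build_dataset(cfg$preset, cfg$n_phantoms, seed = cfg$seed,
                        gt_positions = cfg$gt_positions)
  save_dataset(data, file.path(cfg$out_dir, "dataset.rds"))
  say("stage 2/3: training ", paste(cfg$variants, collapse = ", "))
  tc <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                     k_repeats = max(2L, cfg$k_repeats), seed = cfg$seed)
  n <- dim(data$X)[3]
  sp <- split_dataset(n, tc$split, seed = cfg$seed)
  tr <- dataset_slice(data, sp$train)
  va <- dataset_slice(data, sp$val)
  te <- dataset_slice(data, sp$test)
  nets <- list(); rows <- list()
  for (v in cfg$variants) {
    net <- build_network(net_config(v, fi = cfg$fi), seed = cfg$seed)
    fit <- train_network(net, tr, tc, val = va)
    pred <- net_predict(fit$net, te$X)
    m <- evaluate_pairs(te$Y, pred)
    nets[[v]] <- fit
    rows[[v]] <- cbind(variant = v, m$summary)
  }
  baseline <- evaluate_pairs(te$Y, te$X)
  say("stage 3/3: writing report")
  report <- list(config = unclass(cfg),
                 seeds = list(dataset = cfg$seed, split = cfg$seed,
                              init = cfg$seed),
                 baseline_input = baseline$summary,
                 metrics = lapply(rows, function(r) r))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (requireNamespace("png", quietly = TRUE) && length(sp$test) >= 1) {
    i <- 1
    export_png(te$X[, , i], file.path(cfg$out_dir, "panel_input.png"))
    export_png(nets[[1]]$net |> net_predict(te$X[, , i]),
               file.path(cfg$out_dir, "panel_restored.png"))
    export_png(te$Y[, , i], file.path(cfg$out_dir, "panel_ground_truth.png"))
  }
  list(dataset_path = file.path(cfg$out_dir, "dataset.rds"),
       nets = nets,
       metrics = do.call(rbind, rows),
       baseline_input = baseline$summary,
       report_path = file.path(cfg$out_dir, "report.json"),
       config = cfg)
}

#' Full-scale experiment configuration
#'
#' The stock full-scale protocol (1500 pairs, 100 epochs, 10 resplits,
#' all four architectures at `fi = 32`) as a ready-made [run_config()].
#' This is a multi-day CPU computation provided for completeness; the
#' desk-scale defaults of [run_config()] exercise the identical code
#' path.
#'
#' @param preset `"1ust"` or `"8ust"`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config`.
#' @export
full_scale_config <- function(preset = "1ust", seed = 1,
                              out_dir = "patkit_full_run") {
  p <- pat_preset(preset)
  run_config(preset = preset, n_phantoms = p$n_phantoms,
             variants = c("hd", "fd", "dd", "unet"), fi = 32,
             epochs = 100, batch_size = 2, k_repeats = 10,
             seed = seed, out_dir = out_dir)
}
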