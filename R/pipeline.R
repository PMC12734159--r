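# End-to-end orchestration: config-driven experiment runs (synth ->
# preprocess -> split -> train -> evaluate), the in-memory phantom study
# used for desk-scale validation, and the ablation suite over variants A-F.

#' Reduced model configuration for desk-scale phantom studies
#'
#' The full architecture with all widths divided by four and 96 x 96 inputs
#' — small enough to train on a single CPU core in minutes while preserving
#' every structural component (pooling plan, residual strides, both heads).
#' Head dropout defaults to 0 here: the desk protocol trains on a few
#' hundred images for a handful of epochs, where dropout only slows fitting
#' and would confound architecture comparisons with regularisation
#' strength.
#'
#' @param variant ablation variant letter
#' @param image_side input side, default 96
#' @param dropout head dropout rate, default 0 for desk-scale runs
#' @return a [model_config()]
#' @export
reduced_model_config <- function(variant = "F", image_side = 96L,
                                 dropout = 0) {
  model_config(image_side = image_side,
               spatial_widths = c(8L, 16L, 32L),
               residual_widths = c(32L, 48L, 96L, 128L),
               head_dim = 64L,
               dropout = dropout,
               variant = variant)
}

# Generate preprocessed phantom tensors fully in memory (no PNG round
# trip); returns tensors split into train / internal_val / test.
phantom_tensors <- function(n_per_class, seed, image_side = 96L,
                            noise_sigma = 0.05, lesion_intensity = 0.9,
                            ratio = 0.7, val_frac = 0.15,
                            preprocess = list()) {
  cmap <- phantom_class_map()
  pp <- utils::modifyList(list(unsharp_radius = 100, unsharp_amount = 1.0,
                               sobel_weight = 0.5), preprocess)
  n_total <- 4L * n_per_class
  x <- array(0, dim = c(n_total, 1L, image_side, image_side))
  rows <- vector("list", n_total)
  j <- 0L
  for (ci in seq_along(phantom_class_levels)) {
    cls <- phantom_class_levels[ci]
    for (i in seq_len(n_per_class)) {
      j <- j + 1L
      spec <- phantom_spec(cls, image_side = image_side,
                           noise_sigma = noise_sigma,
                           lesion_intensity = lesion_intensity,
                           seed = mix_seed(seed, ci, i))
      img <- generate_phantom(spec)
      x[j, 1L, , ] <- preprocess_image(img, side = image_side,
                                       unsharp_radius = pp$unsharp_radius,
                                       unsharp_amount = pp$unsharp_amount,
                                       sobel_weight = pp$sobel_weight)
      rows[[j]] <- data.frame(global_id = sprintf("syn-%s-%05d", cmap[[cls]], i),
                              class_label = cmap[[cls]],
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$split <- NA_character_
  manifest <- split_dataset(manifest, ratio = ratio, val_frac = val_frac,
                            seed = mix_seed(seed, 2L))
  class_names <- sort(unique(manifest$class_label))
  pick <- function(split) {
    idx <- which(manifest$split == split)
    list(x = x[idx, , , , drop = FALSE],
         y = match(manifest$class_label[idx], class_names),
         global_id = manifest$global_id[idx],
         class_names = class_names)
  }
  list(train = pick("train"), internal_val = pick("internal_val"),
       test = pick("test"), manifest = manifest)
}

#' Run one phantom training study
#'
#' Generates a seeded four-class phantom set in memory, splits it 7:3 with
#' a 15% internal-validation carve-out, trains the requested variant, and
#' evaluates the best checkpoint on the held-out test portion. All
#' randomness (phantoms, split, weight initialisation, shuffling,
#' augmentation, dropout) derives from `seed`.
#'
#' @param seed integer root seed
#' @param n_per_class phantoms per class (default 100)
#' @param epochs training epochs (default 15)
#' @param variant model variant letter (default `"F"`)
#' @param model base [model_config()]; default [reduced_model_config()]
#' @param train base [train_config()]; its `epochs`/`seed` fields are
#'   overridden by this function's arguments
#' @param noise_sigma phantom noise level
#' @param verbose print per-epoch progress
#' @return list with `checkpoint`, `best_val_acc`, `test_report`, and
#'   `test_accuracy`
#' @export
phantom_study_run <- function(seed, n_per_class = 100L, epochs = 15L,
                              variant = "F", model = reduced_model_config(),
                              train = train_config(learning_rate = 1e-3),
                              noise_sigma = 0.05,
                              verbose = FALSE) {
  model$variant <- variant
  train$epochs <- as.integer(epochs)
  train$seed <- mix_seed(seed, 3L)
  data <- phantom_tensors(n_per_class, seed, image_side = model$image_side,
                          noise_sigma = noise_sigma)
  net <- with_local_seed(mix_seed(seed, 4L), build_model(model))
  ck <- train_tensors(net, data$train, data$internal_val, train,
                      verbose = verbose)
  nn_load_state_dict(net, ck$state)
  ev <- eval_tensors(net, data$test, train$batch_size)
  report <- metrics_report(data$test$y, ev$pred,
                           n_classes = length(data$test$class_names),
                           probs = ev$probs,
                           class_names = data$test$class_names)
  list(checkpoint = ck, best_val_acc = ck$best_val_acc,
       test_report = report, test_accuracy = report$accuracy)
}

#' Ablation suite over model variants
#'
#' Trains the requested variants on identical phantom data and split per
#' seed (so variants differ only architecturally) and tabulates the
#' held-out test accuracy of each variant's best checkpoint. The default
#' protocol matches [phantom_study_run()] — 100 phantoms per class, 15
#' epochs, the reduced dropout-free model — so every variant trains to
#' (near) convergence and the comparison reflects representational
#' differences rather than convergence speed. The comparison of interest is
#' directional (which components help), not absolute accuracy.
#'
#' @param variants subset of `"A"`..`"F"`
#' @param seeds integer vector of root seeds
#' @param n_per_class phantoms per class
#' @param epochs training epochs per run
#' @param model base [model_config()] (variant overridden per run)
#' @param train base [train_config()]
#' @param noise_sigma phantom noise level
#' @param verbose print progress
#' @return list with `results` (variant x seed accuracy data frame) and
#'   `summary` (per-variant mean accuracy)
#' @export
ablation_suite <- function(variants = LETTERS[1:6], seeds = 1:5,
                           n_per_class = 100L, epochs = 15L,
                           model = reduced_model_config(),
                           train = train_config(learning_rate = 1e-3),
                           noise_sigma = 0.05,
                           verbose = FALSE) {
  stopifnot(length(variants) >= 1L, length(seeds) >= 1L)
  variants <- vapply(variants, function(v) match.arg(v, LETTERS[1:6]), "")
  train$epochs <- as.integer(epochs)
  rows <- list()
  for (seed in seeds) {
    data <- phantom_tensors(n_per_class, seed,
                            image_side = model$image_side,
                            noise_sigma = noise_sigma)
    for (v in variants) {
      cfgv <- model
      cfgv$variant <- v
      tc <- train
      tc$seed <- mix_seed(seed, 3L)
      net <- with_local_seed(mix_seed(seed, 4L), build_model(cfgv))
      ck <- train_tensors(net, data$train, data$internal_val, tc)
      nn_load_state_dict(net, ck$state)
      ev <- eval_tensors(net, data$test, tc$batch_size)
      acc <- mean(ev$pred == data$test$y)
      rows[[length(rows) + 1L]] <- data.frame(variant = v, seed = seed,
                                              accuracy = acc)
      if (verbose) {
        message(sprintf("variant %s seed %d: test accuracy %.3f", v, seed, acc))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ variant, results, mean)
  names(summary)[2] <- "mean_accuracy"
  list(results = results, summary = summary)
}

# --- config-driven experiment runner ---------------------------------------

default_experiment_config <- function() {
  list(out_dir = NULL, seed = 1L,
       n_per_class = 50L, image_side = 96L, noise_sigma = 0.05,
       lesion_intensity = 0.9,
       variant = "F",
       spatial_widths = c(8L, 16L, 32L),
       residual_widths = c(32L, 48L, 96L, 128L),
       head_dim = 64L,
       epochs = 15L, batch_size = 32L, learning_rate = 1e-3,
       optimizer = "adamw", weight_decay = 1e-4, dropout = 0,
       augment = TRUE, ratio = 0.7, val_frac = 0.15,
       unsharp_radius = 100, unsharp_amount = 1.0, sobel_weight = 0.5)
}

read_experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_experiment_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  missing <- names(cfg)[vapply(cfg, is.null, logical(1))]
  if (length(missing) > 0) {
    stop("missing required config keys: ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Run a full experiment from a configuration
#'
#' Executes synth -> split -> train -> evaluate, writing every artifact
#' under `out_dir`: the phantom dataset and manifest, the split manifest,
#' the checkpoint, the per-epoch history (TSV), the evaluation report
#' (JSON), and a run record tying them together. Stages whose outputs
#' already exist are skipped unless `force = TRUE`. Per-stage seeds derive
#' from the root seed by a fixed counter scheme (`mix_seed(seed, stage)`),
#' so partial re-runs reproduce the skipped stages' outputs.
#'
#' @param config a named list or the path to a flat YAML file; see
#'   `stripfuse:::default_experiment_config()` for the full key set
#'   (`out_dir` is required)
#' @param force recompute stages whose outputs already exist
#' @return the run record, invisibly (also written as
#'   `<out_dir>/run_record.json`)
#' @export
run_experiment <- function(config, force = FALSE) {
  cfg <- read_experiment_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  snapshot_path <- file.path(out_dir, "config_snapshot.json")
  jsonlite::write_json(cfg[order(names(cfg))], snapshot_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  timings <- c()
  stage <- function(name, output, fn) {
    t0 <- Sys.time()
    ran <- FALSE
    if (force || !all(file.exists(output))) {
      fn()
      ran <- TRUE
    }
    timings[[name]] <<- if (ran) {
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    } else 0
  }

  data_dir <- file.path(out_dir, "data")
  manifest_path <- file.path(data_dir, "manifest.tsv")
  split_path <- file.path(out_dir, "manifest_split.tsv")
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  history_path <- file.path(out_dir, "history.tsv")
  report_path <- file.path(out_dir, "report.json")

  stage("synth", manifest_path, function() {
    generate_phantom_dataset(cfg$n_per_class, data_dir,
                             seed = mix_seed(cfg$seed, 1L),
                             image_side = cfg$image_side,
                             noise_sigma = cfg$noise_sigma,
                             lesion_intensity = cfg$lesion_intensity)
  })
  stage("split", split_path, function() {
    manifest <- read_manifest(manifest_path)
    manifest <- split_dataset(manifest, ratio = cfg$ratio,
                              val_frac = cfg$val_frac,
                              seed = mix_seed(cfg$seed, 2L))
    write_manifest(manifest, split_path)
  })
  pp <- list(unsharp_radius = cfg$unsharp_radius,
             unsharp_amount = cfg$unsharp_amount,
             sobel_weight = cfg$sobel_weight)
  stage("train", c(ckpt_path, history_path), function() {
    manifest <- read_manifest(split_path)
    mcfg <- model_config(image_side = cfg$image_side,
                         spatial_widths = cfg$spatial_widths,
                         residual_widths = cfg$residual_widths,
                         head_dim = cfg$head_dim,
                         dropout = cfg$dropout,
                         variant = cfg$variant)
    tcfg <- train_config(batch_size = cfg$batch_size,
                         learning_rate = cfg$learning_rate,
                         optimizer = cfg$optimizer,
                         weight_decay = cfg$weight_decay,
                         epochs = cfg$epochs, dropout = cfg$dropout,
                         seed = mix_seed(cfg$seed, 3L),
                         augment = cfg$augment)
    net <- with_local_seed(mix_seed(cfg$seed, 4L), build_model(mcfg))
    ck <- train_model(net, manifest, tcfg, preprocess = pp)
    save_checkpoint(ck, ckpt_path)
    utils::write.table(ck$history, history_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  stage("evaluate", report_path, function() {
    manifest <- read_manifest(split_path)
    report <- evaluate_model(ckpt_path, manifest, split = "test",
                             preprocess = pp)
    write_metrics_report(report, report_path)
  })

  record <- list(config = cfg,
                 seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("stripfuse")),
                 hash = unname(tools::md5sum(snapshot_path)),
                 timings_s = as.list(timings),
                 outputs = list(manifest = manifest_path,
                                split_manifest = split_path,
                                checkpoint = ckpt_path,
                                history = history_path,
                                report = report_path))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(record)
}
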