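#' Metrics report directly from confusion counts
#'
#' Convenience wrapper used to reproduce published result tables from the
#' four confusion-matrix cells (melanoma as positive class).
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return a [classification_metrics()] report.
#' @examples
#' metrics_from_counts(tp = 67, fn = 4, fp = 2, tn = 77)$report
#' @export
metrics_from_counts <- function(tp, fn, fp, tn) {
  classification_metrics(confusion_from_counts(tp = tp, fn = fn,
                                               fp = fp, tn = tn))
}

# Default pipeline configuration tree.  Every leaf can be overridden from a
# YAML config file; unknown keys are rejected.
.default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "dermclass_run",
    data = list(source = "synthetic", manifest = NULL,
                n_per_class = 50L, image_size = c(64L, 64L),
                lesion_area_range = c(0.08, 0.25),
                melanoma_effect = list(asymmetry = 2, border_irregularity = 0.3,
                                       color_variance = 2),
                noise = list(gaussian_sigma = 0.02, salt_pepper_fraction = 0.005)),
    preprocess = list(sigma_spatial = 2, sigma_range = 0.1, radius = NULL),
    segment = list(k = 2L, fuzzifier = 2, tol = 1e-5, max_iter = 100L),
    features = list(feature_dim = 32L, input_size = 64L, learning_rate = 0.05,
                    epochs = 30L, batch_size = 8L),
    classifier = list(n_hidden = 10L, threshold = 0.5,
                      activations = c("identity", "logistic", "logistic")),
    mrfo = list(population = 30L, max_iter = 100L, bounds = c(-5, 5),
                somersault_factor = 2),
    evaluate = list(train_fraction = 0.7),
    outputs = list(write_images = FALSE, write_masks = FALSE))
}

# Overlay user values on the default tree, recording unknown-key violations.
.merge_config <- function(default, user, path, violations) {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(default)) {
      violations <- c(violations, sprintf("%s: unknown key", here))
      next
    }
    if (is.list(default[[key]]) && !is.null(names(default[[key]]))) {
      if (!is.list(user[[key]])) {
        violations <- c(violations, sprintf("%s: expected a mapping", here))
        next
      }
      merged <- .merge_config(default[[key]], user[[key]], here, violations)
      default[[key]] <- merged$config
      violations <- merged$violations
    } else {
      default[[key]] <- user[[key]]
    }
  }
  list(config = default, violations = violations)
}

.check_config_values <- function(cfg) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(cfg$data$source %in% c("synthetic", "manifest"),
      "data.source: must be 'synthetic' or 'manifest'")
  if (identical(cfg$data$source, "manifest")) {
    chk(is.character(cfg$data$manifest) && nzchar(cfg$data$manifest),
        "data.manifest: required when data.source is 'manifest'")
  }
  chk(cfg$data$n_per_class >= 0, "data.n_per_class: must be >= 0")
  chk(length(cfg$data$image_size) == 2 && all(cfg$data$image_size >= 16),
      "data.image_size: must be c(height, width), both >= 16")
  lr <- cfg$data$lesion_area_range
  chk(length(lr) == 2 && lr[1] > 0 && lr[2] < 1 && lr[1] < lr[2],
      "data.lesion_area_range: must satisfy 0 < min < max < 1")
  chk(cfg$data$melanoma_effect$asymmetry >= 0,
      "data.melanoma_effect.asymmetry: must be >= 0")
  chk(cfg$data$melanoma_effect$border_irregularity >= 0,
      "data.melanoma_effect.border_irregularity: must be >= 0")
  chk(cfg$data$melanoma_effect$color_variance >= 1,
      "data.melanoma_effect.color_variance: must be >= 1")
  chk(cfg$data$noise$gaussian_sigma >= 0,
      "data.noise.gaussian_sigma: must be >= 0")
  sp <- cfg$data$noise$salt_pepper_fraction
  chk(sp >= 0 && sp <= 1, "data.noise.salt_pepper_fraction: must be in [0, 1]")
  chk(cfg$preprocess$sigma_spatial > 0, "preprocess.sigma_spatial: must be > 0")
  chk(cfg$preprocess$sigma_range > 0, "preprocess.sigma_range: must be > 0")
  chk(is.null(cfg$preprocess$radius) || cfg$preprocess$radius >= 1,
      "preprocess.radius: must be >= 1 (or null for ceiling(3*sigma))")
  chk(cfg$segment$k >= 2, "segment.k: must be >= 2")
  chk(cfg$segment$fuzzifier > 1, "segment.fuzzifier: must satisfy the '>1' constraint")
  chk(cfg$segment$tol > 0, "segment.tol: must be > 0")
  chk(cfg$segment$max_iter >= 1, "segment.max_iter: must be >= 1")
  chk(cfg$features$feature_dim >= 2, "features.feature_dim: must be >= 2")
  chk(cfg$features$learning_rate >= 0, "features.learning_rate: must be >= 0")
  chk(cfg$features$epochs >= 1, "features.epochs: must be >= 1")
  chk(cfg$features$batch_size >= 1, "features.batch_size: must be >= 1")
  chk(cfg$classifier$n_hidden >= 1, "classifier.n_hidden: must be >= 1")
  chk(cfg$classifier$threshold >= 0 && cfg$classifier$threshold <= 1,
      "classifier.threshold: must be in [0, 1]")
  chk(all(cfg$classifier$activations %in% c("identity", "logistic", "tanh")) &&
        length(cfg$classifier$activations) == 3,
      "classifier.activations: must be 3 of identity/logistic/tanh")
  chk(cfg$mrfo$population >= 2, "mrfo.population: must be >= 2")
  chk(cfg$mrfo$max_iter >= 1, "mrfo.max_iter: must be >= 1")
  b <- cfg$mrfo$bounds
  chk(length(b) == 2 && b[1] < b[2], "mrfo.bounds: must be c(lower, upper), lower < upper")
  chk(cfg$mrfo$somersault_factor > 0, "mrfo.somersault_factor: must be > 0")
  tf <- cfg$evaluate$train_fraction
  chk(tf > 0 && tf < 1, "evaluate.train_fraction: must be in (0, 1)")
  v
}

#' Validate a pipeline configuration
#'
#' Parses YAML (a file path, literal YAML text, or an already-parsed list),
#' overlays it on the package defaults, and checks every constraint,
#' reporting *all* violations (field path plus constraint) rather than just
#' the first.  Unknown keys are errors so config typos cannot silently fall
#' back to defaults.  An empty input yields the full default configuration.
#'
#' @param x path to a YAML file, a YAML string, a list, or `NULL`.
#' @return a validated `run_config` object (the defaulted config tree).
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) {
    list()
  } else if (is.list(x)) {
    x
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(x)
  }
  if (is.null(user)) user <- list()   # empty file parses to NULL
  merged <- .merge_config(.default_run_config(), user, "", character(0))
  cfg <- merged$config
  violations <- c(merged$violations, .check_config_values(cfg))
  if (length(violations)) {
    stop(paste0("invalid configuration:\n  ",
                paste(violations, collapse = "\n  ")), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

# Deterministic fan-out of the single global seed to per-stage seeds.
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 100 + stage) %% .Machine$integer.max
}

#' Run the full classification pipeline
#'
#' Executes generate (or load) -> bilateral filter -> fuzzy k-means
#' segmentation -> CNN feature extraction -> MRFO training of the
#' cascade-forward classifier -> evaluation, in that order, from a single
#' validated configuration.  Every stage's seed is derived from the global
#' seed, so the run (including the metrics files it writes) is fully
#' reproducible.  Extracted features are standardized with the training
#' split's mean and standard deviation before classification.
#'
#' @param config a `run_config` from [validate_config()] (or anything
#'   [validate_config()] accepts).
#' @param verbose print stage progress.
#' @return a `run_manifest` list: configuration hash, per-stage timings
#'   (seconds), artifact paths, per-stage summaries (mean training Dice,
#'   extractor loss history, MRFO trace) and the final test-set
#'   [classification_metrics()] report.
#' @export
run_pipeline <- function(config = validate_config(), verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t_all <- proc.time()[["elapsed"]]
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(name, start) {
    timings[[name]] <<- proc.time()[["elapsed"]] - start
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stage 1: data ------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (config$data$source == "synthetic") {
    sc <- synth_config(n_per_class = config$data$n_per_class,
                       image_size = config$data$image_size,
                       lesion_area_range = config$data$lesion_area_range,
                       melanoma_effect = config$data$melanoma_effect,
                       noise = config$data$noise,
                       seed = .stage_seed(config$seed, 1))
    dataset <- generate_dataset(sc)
  } else {
    dataset <- read_dataset(config$data$manifest)
  }
  if (length(dataset) < 4L) {
    stop("pipeline stage `data` failed: need at least 4 labelled images", call. = FALSE)
  }
  labels <- vapply(dataset, `[[`, character(1), "label")
  tick("data", t0)
  say("data: %d images", length(dataset))

  # -- stage 2: preprocessing --------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bp <- bilateral_params(config$preprocess$sigma_spatial,
                         config$preprocess$sigma_range,
                         config$preprocess$radius)
  filtered <- lapply(dataset, function(d) bilateral_filter(d$image, bp))
  tick("preprocess", t0)

  # -- stage 3: segmentation ---------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  fc <- fkm_config(k = config$segment$k, fuzzifier = config$segment$fuzzifier,
                   tol = config$segment$tol, max_iter = config$segment$max_iter,
                   seed = .stage_seed(config$seed, 3))
  masks <- lapply(filtered, function(img) segment_image(img, fc)$mask)
  dice <- rep(NA_real_, length(dataset))
  for (i in seq_along(dataset)) {
    if (!is.null(dataset[[i]]$truth_mask)) {
      dice[i] <- dice_coefficient(masks[[i]], dataset[[i]]$truth_mask)
    }
  }
  tick("segment", t0)
  say("segment: mean Dice vs truth = %.3f", mean(dice, na.rm = TRUE))

  # -- stage 4: split -----------------------------------------------------
  split <- stratified_split(labels, config$evaluate$train_fraction,
                            seed = .stage_seed(config$seed, 4))

  # -- stage 5: feature extraction ---------------------------------------
  t0 <- proc.time()[["elapsed"]]
  ec <- extractor_config(feature_dim = config$features$feature_dim,
                         input_size = config$features$input_size,
                         sgd = list(learning_rate = config$features$learning_rate,
                                    epochs = config$features$epochs,
                                    batch_size = config$features$batch_size),
                         seed = .stage_seed(config$seed, 5))
  train_items <- lapply(split$train, function(i)
    list(image = filtered[[i]], label = labels[i], id = dataset[[i]]$id))
  extractor <- train_extractor(train_items, masks = masks[split$train],
                               config = ec)
  all_items <- lapply(seq_along(dataset), function(i)
    list(image = filtered[[i]], label = labels[i], id = dataset[[i]]$id))
  feats <- extract_features_dataset(extractor, all_items, masks = masks)
  mu <- colMeans(feats[split$train, , drop = FALSE])
  sdv <- apply(feats[split$train, , drop = FALSE], 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  feats_std <- sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
  tick("features", t0)
  say("features: final training loss %.4f", utils::tail(extractor$loss_history, 1))

  # -- stage 6: classifier training (MRFO) --------------------------------
  t0 <- proc.time()[["elapsed"]]
  mc <- mrfo_config(population = config$mrfo$population,
                    max_iter = config$mrfo$max_iter,
                    bounds = config$mrfo$bounds,
                    somersault_factor = config$mrfo$somersault_factor,
                    seed = .stage_seed(config$seed, 6))
  trained <- train_cascade_mrfo(feats_std[split$train, , drop = FALSE],
                                labels[split$train],
                                n_hidden = config$classifier$n_hidden,
                                activations = config$classifier$activations,
                                config = mc)
  tick("train", t0)
  say("train: MRFO training error %.2f%%", trained$best_fitness)

  # -- stage 7: evaluation ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  test_X <- feats_std[split$test, , drop = FALSE]
  test_y <- labels[split$test]
  scores <- cascade_forward(trained$params, test_X)
  pred <- ifelse(scores >= config$classifier$threshold, "melanoma", "benign")
  cm <- confusion_matrix2(test_y, pred)
  metrics <- classification_metrics(cm)
  roc <- roc_points(test_y, scores)
  pr <- pr_points(test_y, scores)
  tick("evaluate", t0)
  say("evaluate: test accuracy %.2f%%", metrics$unrounded$accuracy)

  # -- artifacts ----------------------------------------------------------
  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    metrics_json = file.path(out_dir, "metrics.json"),
    metrics_csv = file.path(out_dir, "metrics.csv"),
    features_csv = file.path(out_dir, "features.csv"),
    trace_csv = file.path(out_dir, "mrfo_trace.csv"),
    model = file.path(out_dir, "cascade_model.yaml"),
    roc_csv = file.path(out_dir, "roc_points.csv"),
    pr_csv = file.path(out_dir, "pr_points.csv"))
  yaml::write_yaml(unclass(config), paths$config)
  jsonlite::write_json(
    list(confusion = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn),
         report = metrics$report,
         unrounded = metrics$unrounded,
         roc_auc = roc$auc, pr_auc = pr$auc,
         mean_dice = mean(dice, na.rm = TRUE),
         seed = config$seed),
    paths$metrics_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(metrics$report, paths$metrics_csv, row.names = FALSE)
  fdf <- data.frame(id = rownames(feats), label = labels,
                    split = ifelse(seq_along(labels) %in% split$train,
                                   "train", "test"))
  fdf <- cbind(fdf, as.data.frame(feats))
  names(fdf)[-(1:3)] <- sprintf("f_%02d", seq_len(ncol(feats)) - 1L)
  utils::write.csv(fdf, paths$features_csv, row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(trained$trace),
                              best_fitness = trained$trace),
                   paths$trace_csv, row.names = FALSE)
  write_cascade_model(trained$params, paths$model)
  utils::write.csv(roc$points, paths$roc_csv, row.names = FALSE)
  utils::write.csv(pr$points, paths$pr_csv, row.names = FALSE)
  if (isTRUE(config$outputs$write_masks)) {
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (i in seq_along(masks)) {
      write_image(masks[[i]], file.path(mask_dir, paste0(dataset[[i]]$id, "_mask.png")))
    }
  }
  if (isTRUE(config$outputs$write_images)) {
    write_dataset(dataset, file.path(out_dir, "images"))
  }
  timings[["total"]] <- proc.time()[["elapsed"]] - t_all

  structure(list(
    config_hash = unname(tools::md5sum(paths$config)),
    timings = timings,
    paths = paths,
    n_train = length(split$train), n_test = length(split$test),
    split = split,
    mean_dice = mean(dice, na.rm = TRUE),
    extractor_loss = extractor$loss_history,
    mrfo_trace = trained$trace,
    train_error_rate = trained$best_fitness,
    scores = scores,
    metrics = metrics,
    roc = roc, pr = pr),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("dermclass pipeline run\n")
  cat(sprintf("  images: %d train / %d test; mean Dice %.3f\n",
              x$n_train, x$n_test, x$mean_dice))
  cat(sprintf("  MRFO training error: %.2f%%\n", x$train_error_rate))
  cat(sprintf("  test accuracy: %.2f%% (ROC AUC %.3f)\n",
              x$metrics$accuracy, x$roc$auc))
  invisible(x)
}

#' Serialize a cascade-forward model as structured text
#'
#' Models are written as YAML (layout header plus flat weight vector) so
#' that runs are diffable and text-only.
#'
#' @param params a [cascade_params()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cascade_model <- function(params, path) {
  stopifnot(inherits(params, "cascade_params"))
  v <- flatten_params(params)
  yaml::write_yaml(list(
    type = "cascade_forward",
    n_inputs = params$n_inputs, n_hidden = params$n_hidden,
    activations = as.list(params$activations),
    values = as.numeric(v)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_cascade_model
#' @export
read_cascade_model <- function(path) {
  m <- yaml::read_yaml(path)
  layout <- param_layout(m$n_inputs, m$n_hidden, unlist(m$activations))
  unflatten_params(as.numeric(m$values), layout)
}
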