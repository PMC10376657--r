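#' Derive a reproducible stage seed from the master seed
#'
#' Stage seeds are a deterministic polynomial hash of the stage name folded
#' with the master seed, reduced below 2^31, so every stage is reproducible
#' in isolation.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
stage_seed <- function(master, stage) {
  h <- 17
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(master) * 2654435761) %% 2147483646) + 1L
}

#' Experiment configuration
#'
#' Everything needed to run the full simulate -> filter -> t-map -> train ->
#' evaluate experiment. Defaults reproduce the study conditions: 11 subjects,
#' 6 trials, the eight initial-dip windows (0.5-4 s) plus the 14 s delayed
#' window, depth-22 network. `image_size`, `base_filters` and `epochs` set
#' the computational scale.
#'
#' @param n_subjects,n_trials Cohort size.
#' @param windows Initial-dip analysis windows (seconds).
#' @param delayed_window_s Delayed-response comparison window (seconds).
#' @param depths CNN depths to run.
#' @param image_size Rendered t-map side length in pixels.
#' @param base_filters First-block filter count of the CNN.
#' @param train A `train_config`.
#' @param profiles List with `RHTF`/`RHLF` `activation_profile`s.
#' @param noise A `noise_params`.
#' @param hrf A `gamma_hrf_params`.
#' @param fspec A `filter_spec`.
#' @param tmap A `tmap_params` (its `image_size` is overridden).
#' @param protocol A `session_protocol`.
#' @param geometry A `channel_geometry`, or a path to a geometry JSON file.
#' @param seed Master seed.
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 11, n_trials = 6,
                              windows = seq(0.5, 4, by = 0.5),
                              delayed_window_s = 14,
                              depths = 22,
                              image_size = 112, base_filters = 6,
                              train = train_config(epochs = 25, batch_size = 16),
                              profiles = default_profiles(),
                              noise = noise_params(),
                              hrf = gamma_hrf_params(),
                              fspec = NULL,
                              tmap = tmap_params(),
                              protocol = session_protocol(),
                              geometry = grid_geometry(),
                              seed = 1, out_dir = NULL) {
  if (is.character(geometry)) {
    if (!file.exists(geometry))
      stop("configuration error: geometry file not found: ", geometry,
           call. = FALSE)
    geometry <- read_geometry_json(geometry)
  }
  if (is.null(fspec)) fspec <- filter_spec(fs = protocol$fs)
  trial_len <- protocol$task_s + protocol$rest_s
  if (any(c(windows, delayed_window_s) <= 0) ||
      any(c(windows, delayed_window_s) > trial_len))
    stop("windows must lie in (0, trial length]", call. = FALSE)
  tmap$image_size <- as.integer(image_size)
  structure(list(n_subjects = n_subjects, n_trials = n_trials,
                 windows = windows, delayed_window_s = delayed_window_s,
                 depths = depths, image_size = as.integer(image_size),
                 base_filters = base_filters, train = train,
                 profiles = profiles, noise = noise, hrf = hrf,
                 fspec = fspec, tmap = tmap, protocol = protocol,
                 geometry = geometry, seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

run_depth <- function(ds, depth, config, regime) {
  arch <- cnn_architecture(depth, input_size = config$image_size,
                           base_filters = config$base_filters)
  sp <- split_dataset(ds, ratio = config$train$split,
                      seed = stage_seed(config$seed, paste0("split_", regime)))
  tc <- config$train
  tc$seed <- stage_seed(config$seed, sprintf("train_%s_d%d", regime, depth))
  model <- train_cnn(arch, sp$train, tc)
  pred <- predict_cnn(model, sp$validation)
  cm <- confusion(sp$validation$labels, pred$labels)
  metrics <- eq1_metrics(cm)
  roc <- lapply(c("RHTF", "RHLF"), function(cl)
    roc_auc(pred$scores[, cl], sp$validation$labels, positive = cl))
  names(roc) <- c("RHTF", "RHLF")
  list(depth = depth, regime = regime,
       n_train = dim(sp$train$images)[4],
       n_validation = dim(sp$validation$images)[4],
       n_validation_per_class = as.vector(table(sp$validation$labels)),
       confusion = cm, metrics = metrics,
       accuracy = metrics$accuracy / 100,
       auc = vapply(roc, `[[`, numeric(1), "auc"),
       roc = lapply(roc, `[[`, "roc"),
       model = model, curves = model$curves)
}

#' Run the full initial-dip classification experiment
#'
#' Simulates the cohort, band-pass filters it, builds t-map image datasets
#' for (a) each initial-dip window separately, (b) all dip windows combined,
#' and (c) the delayed 14 s window, then trains and evaluates the CNN at
#' every requested depth on the combined and delayed datasets (and reports
#' per-window dataset sizes). All stage randomness derives from
#' `config$seed` via [stage_seed()].
#'
#' @param config An `experiment_config`.
#' @param per_window_training Also train on every single-window dataset
#'   (slower; the headline comparison needs only combined vs. delayed).
#' @param progress Print stage progress.
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(config = experiment_config(),
                           per_window_training = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  stage <- "simulate"
  report <- tryCatch({
    say("stage simulate: %d subjects x 2 sessions", config$n_subjects)
    cohort <- make_cohort(config$n_subjects, config$n_trials,
                          config$profiles$RHTF, config$profiles$RHLF,
                          config$noise,
                          seed = stage_seed(config$seed, "simulate"),
                          protocol = config$protocol,
                          geometry = config$geometry, hrf = config$hrf)
    stage <- "tmap"
    say("stage tmap: %d dip windows + %g s delayed", length(config$windows),
        config$delayed_window_s)
    ds_combined <- build_tmap_dataset(cohort, config$windows, config$tmap,
                                      config$fspec, config$hrf)
    ds_delayed <- build_tmap_dataset(cohort, config$delayed_window_s,
                                     config$tmap, config$fspec, config$hrf)
    per_window <- lapply(config$windows, function(w)
      which(ds_combined$meta$window_s == w))
    names(per_window) <- sprintf("%gs", config$windows)

    stage <- "train"
    runs <- list()
    for (depth in config$depths) {
      say("stage train: depth %d (combined, %d images)", depth,
          dim(ds_combined$images)[4])
      runs[[sprintf("combined_d%d", depth)]] <-
        run_depth(ds_combined, depth, config, "combined")
      say("stage train: depth %d (delayed %g s)", depth,
          config$delayed_window_s)
      runs[[sprintf("delayed_d%d", depth)]] <-
        run_depth(ds_delayed, depth, config, "delayed")
      if (per_window_training) {
        for (w in names(per_window)) {
          dsw <- subset_dataset(ds_combined, per_window[[w]])
          runs[[sprintf("window_%s_d%d", w, depth)]] <-
            run_depth(dsw, depth, config, paste0("window_", w))
        }
      }
    }
    stage <- "evaluate"
    summary <- do.call(rbind, lapply(runs, function(r)
      data.frame(regime = r$regime, depth = r$depth, n_train = r$n_train,
                 n_validation = r$n_validation,
                 accuracy = r$accuracy,
                 accuracy_pct = r$metrics$accuracy_rounded,
                 auc_RHTF = r$auc[["RHTF"]], auc_RHLF = r$auc[["RHLF"]])))
    rownames(summary) <- NULL
    structure(list(config = config, runs = runs, summary = summary,
                   per_window_n = vapply(per_window, length, integer(1)),
                   n_per_class_combined = as.vector(table(ds_combined$labels)),
                   n_per_class_delayed = as.vector(table(ds_delayed$labels)),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
              class = "experiment_report")
  }, error = function(e) {
    stop(sprintf("experiment aborted in stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  print(x$summary)
  invisible(x)
}

#' Write an experiment report (JSON + curves/ROC CSV + manifest)
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  json <- list(
    seed = report$config$seed,
    summary = report$summary,
    per_window_n = as.list(report$per_window_n),
    n_per_class_combined = report$n_per_class_combined,
    n_per_class_delayed = report$n_per_class_delayed,
    runs = lapply(report$runs, function(r)
      list(regime = r$regime, depth = r$depth, accuracy = r$accuracy,
           confusion = unclass(r$confusion), auc = as.list(r$auc),
           n_train = r$n_train, n_validation = r$n_validation)),
    elapsed_s = report$elapsed_s)
  f <- file.path(dir, "report.json")
  jsonlite::write_json(json, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  for (nm in names(report$runs)) {
    f <- file.path(dir, sprintf("curves_%s.csv", nm))
    utils::write.csv(report$runs[[nm]]$curves, f, row.names = FALSE)
    files <- c(files, f)
    for (cl in names(report$runs[[nm]]$roc)) {
      f <- file.path(dir, sprintf("roc_%s_%s.csv", nm, cl))
      utils::write.csv(report$runs[[nm]]$roc[[cl]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  write_manifest(files, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read/write an experiment config as YAML (scalar fields)
#' @param config An `experiment_config`.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(list(
    n_subjects = config$n_subjects, n_trials = config$n_trials,
    windows = config$windows, delayed_window_s = config$delayed_window_s,
    depths = config$depths, image_size = config$image_size,
    base_filters = config$base_filters,
    epochs = config$train$epochs, learn_rate = config$train$learn_rate,
    momentum = config$train$momentum, batch_size = config$train$batch_size,
    split = config$train$split, seed = config$seed), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_config(
    n_subjects = x$n_subjects, n_trials = x$n_trials, windows = x$windows,
    delayed_window_s = x$delayed_window_s, depths = x$depths,
    image_size = x$image_size, base_filters = x$base_filters,
    train = train_config(epochs = x$epochs, learn_rate = x$learn_rate,
                         momentum = x$momentum, batch_size = x$batch_size,
                         split = x$split, seed = x$seed),
    seed = x$seed)
}
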