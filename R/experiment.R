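#' Default hyperparameter sweep grids
#'
#' The grids used to tune the model: square kernel sides 1-7, kernel counts
#' {4, 8, 16, 32, 64, 128}, LSTM units {16, 32, 64, 128, 256} and dropout
#' 0.1-0.9 in steps of 0.1. The learning rate is searched in two stages via
#' [sweep_learning_rate()].
#'
#' @return A named list of candidate vectors.
#' @export
default_sweep_grids <- function() {
  list(
    kernel_size = 1:7,
    n_kernels = c(4, 8, 16, 32, 64, 128),
    lstm_units = c(16, 32, 64, 128, 256),
    dropout = seq(0.1, 0.9, by = 0.1)
  )
}

#' Sweep one model hyperparameter
#'
#' Trains one model per candidate value and repetition, holding every other
#' setting at `base_config` / `train_cfg`, and reports the mean validation
#' accuracy per candidate. Candidates incompatible with the input shape are
#' recorded as failed cells and the sweep continues.
#'
#' @param dataset A `windowed_dataset`.
#' @param parameter One of `"kernel_size"`, `"n_kernels"`, `"lstm_units"`,
#'   `"dropout"`, `"learning_rate"`.
#' @param values Candidate values; defaults to [default_sweep_grids()].
#' @param base_config A [model_config()] supplying the held-fixed settings.
#' @param train_cfg A [train_config()].
#' @param repetitions Training runs per candidate (different seeds); default 3.
#' @param verbose Print progress lines.
#' @return A list with `runs` (tibble: value, repetition, seed, accuracy,
#'   error) and `summary` (tibble: value, mean validation accuracy, number
#'   of successful runs).
#' @export
run_sweep <- function(dataset, parameter, values = NULL, base_config,
                      train_cfg = train_config(), repetitions = 3,
                      verbose = FALSE) {
  parameter <- match.arg(parameter,
                         c("kernel_size", "n_kernels", "lstm_units",
                           "dropout", "learning_rate"))
  if (is.null(values)) {
    values <- default_sweep_grids()[[parameter]]
    if (is.null(values)) stop("no default grid for `", parameter,
                              "`; supply `values`", call. = FALSE)
  }
  stopifnot(length(values) >= 1, repetitions >= 1)
  runs <- list()
  for (v in values) {
    for (rep_i in seq_len(repetitions)) {
      seed <- train_cfg$seed + 1000L * (rep_i - 1L)
      cfg <- base_config
      tcfg <- train_cfg
      tcfg$seed <- seed
      if (parameter == "learning_rate") {
        tcfg$learning_rate <- v
      } else {
        cfg[[parameter]] <- if (parameter == "dropout") v else as.integer(v)
      }
      acc <- NA_real_
      err <- NA_character_
      res <- tryCatch({
        fit <- fit_res_bilstm(cfg, dataset, tcfg)
        acc <- fit$history$val_accuracy[nrow(fit$history)]
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) err <- res
      if (verbose) {
        message(sprintf("%s = %s (rep %d): %s", parameter, format(v), rep_i,
                        if (is.na(acc)) paste("failed:", err) else
                          sprintf("val acc %.4f", acc)))
      }
      runs[[length(runs) + 1L]] <- tibble::tibble(
        value = v, repetition = rep_i, seed = seed,
        accuracy = acc, error = err
      )
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$value),
    mean_val_accuracy = mean(.data$accuracy, na.rm = TRUE),
    n_ok = sum(!is.na(.data$accuracy)),
    .groups = "drop"
  )
  list(parameter = parameter, runs = runs, summary = summary)
}

#' Two-stage learning-rate search
#'
#' First compares decade-spaced coarse candidates, then scans the winning
#' decade with a step of one tenth of that decade (e.g. a winner of 1e-4
#' leads to a fine grid 1e-4, 2e-4, ..., 1e-3).
#'
#' @inheritParams run_sweep
#' @param coarse Coarse candidates; default `c(1e-5, 1e-4, 1e-3, 1e-2)`.
#' @return A list with `coarse` and `fine` sweep results and `best`, the
#'   fine-stage winner.
#' @export
sweep_learning_rate <- function(dataset, base_config,
                                train_cfg = train_config(),
                                coarse = c(1e-5, 1e-4, 1e-3, 1e-2),
                                repetitions = 1, verbose = FALSE) {
  stage1 <- run_sweep(dataset, "learning_rate", coarse, base_config,
                      train_cfg, repetitions, verbose)
  win <- stage1$summary$value[which.max(stage1$summary$mean_val_accuracy)]
  fine_values <- seq(win, win * 10, by = win)
  stage2 <- run_sweep(dataset, "learning_rate", fine_values, base_config,
                      train_cfg, repetitions, verbose)
  best <- stage2$summary$value[which.max(stage2$summary$mean_val_accuracy)]
  list(coarse = stage1, fine = stage2, best = best)
}

#' Run a full experiment from a configuration
#'
#' One call that covers the whole pipeline: load or generate the data,
#' standardize, window, train, and evaluate. The configuration is a plain
#' named list (or a YAML file path with the same structure):
#'
#' * `dataset`: either `list(source = "synthetic", total_duration = ...,
#'   seed = ...)` or `list(source = "csv"/"wisdm"/"pamap2", path = ...,
#'   validation_subjects = ...)`
#' * `window`: `list(length = 100, overlap = 0.5)`
#' * `model`: overrides for [model_config()] (`n_kernels`, `kernel_size`,
#'   `lstm_units`, `dropout`)
#' * `train`: overrides for [train_config()] plus `validation_split`
#' * `out_dir`: optional directory for artifacts (history CSV, confusion
#'   matrix CSV, metric report, JSON summary)
#'
#' When `validation_subjects` is given, every window of those subjects forms
#' the validation set instead of a random split.
#'
#' @param config A named list or path to a YAML file.
#' @param verbose Print per-epoch progress.
#' @return A list with the fitted model (`fit`), the `windowed_dataset`,
#'   the validation `confusion` matrix, `metrics` tibble, `accuracy`,
#'   `weighted_f1` and the effective `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dcfg <- config$dataset %||% list(source = "synthetic")
  wcfg <- config$window %||% list()
  mcfg <- config$model %||% list()
  tcfg <- config$train %||% list()

  recordings <- switch(
    dcfg$source %||% "synthetic",
    synthetic = generate_imu_dataset(generator_config(
      total_duration = dcfg$total_duration %||% 1800,
      n_subjects = dcfg$n_subjects %||% 5,
      seed = dcfg$seed %||% 1
    )),
    csv = read_imu_csv(dcfg$path, dataset_manifest(
      "csv", channels = dcfg$channels,
      sample_rate = dcfg$sample_rate %||% 50
    )),
    wisdm = read_wisdm(dcfg$path),
    pamap2 = read_pamap2(dcfg$path, subjects = dcfg$subjects),
    stop("unknown dataset source `", dcfg$source, "`", call. = FALSE)
  )

  recordings <- standardize_channels(recordings)
  ds <- segment_windows(recordings,
                        window_length = wcfg$length %||% 100,
                        overlap = wcfg$overlap %||% 0.5)

  model_cfg <- model_config(
    window_length = ds$window_length,
    n_channels = length(ds$channels),
    n_classes = length(ds$class_levels),
    n_kernels = mcfg$n_kernels %||% 32,
    kernel_size = mcfg$kernel_size %||% 2,
    lstm_units = mcfg$lstm_units %||% 64,
    dropout = mcfg$dropout %||% 0.5
  )
  train_cfg <- train_config(
    learning_rate = tcfg$learning_rate %||% 3e-4,
    batch_size = tcfg$batch_size %||% 64,
    epochs = tcfg$epochs %||% 80,
    seed = tcfg$seed %||% 1
  )
  val_idx <- NULL
  if (!is.null(dcfg$validation_subjects)) {
    val_idx <- which(ds$provenance$subject %in% dcfg$validation_subjects)
  }
  fit <- fit_res_bilstm(model_cfg, ds, train_cfg,
                        validation_split = tcfg$validation_split %||% 0.3,
                        validation_indices = val_idx, verbose = verbose)

  val <- fit$val_indices
  pred <- predict(fit, ds$windows[val, , , drop = FALSE], type = "class")
  cm <- confusion_matrix(as.character(ds$labels[val]), as.character(pred),
                         levels = ds$class_levels)
  metrics <- suppressWarnings(per_class_metrics(cm))
  acc <- accuracy(cm)
  fw <- tryCatch(weighted_f1(metrics), error = function(e) NA_real_)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fit$history, file.path(config$out_dir, "history.csv"))
    utils::write.csv(unclass(cm), file.path(config$out_dir, "confusion.csv"))
    readr::write_csv(metrics, file.path(config$out_dir, "metrics.csv"))
    writeLines(
      apply(format_metric_table(cm), 1, paste, collapse = "\t"),
      file.path(config$out_dir, "confusion_report.txt")
    )
    jsonlite::write_json(
      list(accuracy = acc, weighted_f1 = fw,
           parameters = count_parameters(fit$model),
           epochs = nrow(fit$history)),
      file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(fit = fit, dataset = ds, confusion = cm, metrics = metrics,
       accuracy = acc, weighted_f1 = fw, config = config)
}
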