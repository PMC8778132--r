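test_that("a sweep trains candidates x repetitions and tabulates accuracies", {
  ds <- make_separable_dataset(n_per_class = 12, L = 10, C = 2, seed = 5)
  base <- model_config(10, 2, 2, n_kernels = 2, lstm_units = 2)
  sw <- run_sweep(ds, "lstm_units", values = c(2, 4), base_config = base,
                  train_cfg = train_config(epochs = 1, seed = 1),
                  repetitions = 2)
  expect_equal(nrow(sw$runs), 4)
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$n_ok, c(2L, 2L))
  expect_true(all(is.finite(sw$summary$mean_val_accuracy)))
  # repetitions use distinct seeds
  expect_equal(dplyr::n_distinct(sw$runs$seed), 2)
})

test_that("an infeasible candidate is recorded as failed, not fatal", {
  ds <- make_separable_dataset(n_per_class = 8, L = 6, C = 2, seed = 6)
  base <- model_config(6, 2, 2, n_kernels = 2, lstm_units = 2)
  sw <- run_sweep(ds, "kernel_size", values = c(2, 7), base_config = base,
                  train_cfg = train_config(epochs = 1, seed = 1),
                  repetitions = 1)
  expect_true(is.na(sw$runs$accuracy[sw$runs$value == 7]))
  expect_false(is.na(sw$runs$accuracy[sw$runs$value == 2]))
  expect_match(sw$runs$error[sw$runs$value == 7], "too short")
})

test_that("the two-stage learning-rate search reports both stages", {
  ds <- make_separable_dataset(n_per_class = 8, L = 10, C = 2, seed = 7)
  base <- model_config(10, 2, 2, n_kernels = 2, lstm_units = 2)
  lr <- sweep_learning_rate(ds, base, train_config(epochs = 1, seed = 1),
                            coarse = c(1e-3, 1e-2))
  expect_equal(nrow(lr$coarse$summary), 2)
  expect_equal(nrow(lr$fine$summary), 10)
  # the fine grid steps by a tenth of the winning decade
  win <- lr$coarse$summary$value[which.max(lr$coarse$summary$mean_val_accuracy)]
  expect_equal(lr$fine$summary$value, seq(win, win * 10, by = win))
  expect_true(lr$best %in% lr$fine$summary$value)
})

test_that("run_experiment drives the full pipeline and writes artifacts", {
  out <- withr::local_tempdir()
  res <- run_experiment(list(
    dataset = list(source = "synthetic", total_duration = 120,
                   n_subjects = 2, seed = 9),
    window = list(length = 50, overlap = 0.5),
    model = list(n_kernels = 8, lstm_units = 16),
    train = list(epochs = 2, learning_rate = 1e-3, seed = 2),
    out_dir = out
  ))
  expect_s3_class(res$confusion, "confusion_matrix")
  expect_equal(dim(res$confusion), c(6, 6))
  expect_equal(nrow(res$metrics), 6)
  expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  for (f in c("history.csv", "confusion.csv", "metrics.csv",
              "confusion_report.txt", "summary.json")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$parameters, count_parameters(res$fit$model))
})

test_that("run_experiment honours a subject-wise validation split", {
  out <- run_experiment(list(
    dataset = list(source = "synthetic", total_duration = 120, n_subjects = 2,
                   seed = 10, validation_subjects = "subj02"),
    window = list(length = 50),
    model = list(n_kernels = 2, lstm_units = 2),
    train = list(epochs = 1, seed = 3)
  ))
  prov <- out$dataset$provenance
  expect_setequal(unique(prov$subject[out$fit$val_indices]), "subj02")
  expect_setequal(unique(prov$subject[out$fit$train_indices]), "subj01")
})

test_that("invalid experiment configs fail before any training", {
  expect_error(run_experiment(list(dataset = list(source = "nope"))),
               "unknown dataset source")
})

test_that("yaml configs are accepted", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dataset:",
    "  source: synthetic",
    "  total_duration: 60",
    "  n_subjects: 1",
    "  seed: 4",
    "window:",
    "  length: 50",
    "model:",
    "  n_kernels: 2",
    "  lstm_units: 2",
    "train:",
    "  epochs: 1",
    "  seed: 5"
  ), f)
  res <- run_experiment(f)
  expect_s3_class(res$fit, "res_bilstm_fit")
})
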