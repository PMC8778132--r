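test_that("stride-2 same convolutions halve both axes, rounding up", {
  withr::local_seed(4)
  for (i in 1:30) {
    L <- sample(2:128, 1); C <- sample(1:128, 1)
    cfg <- model_config(L, C, 3)
    shp <- resbilstm:::seq_stage_shape(cfg)
    expect_equal(shp[["steps"]], ceiling(L / 2))
    expect_equal(shp[["features"]], ceiling(C / 2) * 32)
  }
  # realized activations agree with the arithmetic
  m <- build_res_bilstm(model_config(7, 5, 2, n_kernels = 4, lstm_units = 3),
                        seed = 1)
  fwd <- resbilstm:::model_forward(m, array(rnorm(2 * 7 * 5), c(2, 7, 5)),
                                   training = TRUE)
  expect_equal(fwd$cache$map_dims, c(2, 4, 3, 4))
})

test_that("trainable parameter totals match the per-layer arithmetic", {
  # 40-sample x 3-channel windows, 6 classes: published total
  expect_identical(count_parameters(model_config(40, 3, 6)), 71462L)
  # 100 x 6, 6 classes: conv block 4640 + BiLSTM 82432 + dense 774
  expect_identical(count_parameters(model_config(100, 6, 6)), 87846L)
  # 100 x 18, 12 classes: full total including the 1548-parameter head
  expect_identical(count_parameters(model_config(100, 18, 12)), 186924L)
})

test_that("parameter count is independent of window length", {
  counts <- vapply(c(40, 100, 200),
                   function(L) count_parameters(model_config(L, 3, 6)),
                   integer(1))
  expect_identical(counts, rep(counts[1], 3))
})

test_that("summary totals equal the instantiated parameter arrays", {
  for (cfg in list(model_config(40, 3, 6), model_config(100, 18, 12),
                   model_config(30, 5, 4, n_kernels = 8, kernel_size = 3,
                                lstm_units = 16))) {
    m <- build_res_bilstm(cfg, seed = 1)
    expect_identical(count_parameters(m), count_parameters(cfg))
    s <- architecture_summary(m)
    expect_identical(count_parameters(s), sum(s$params) |> as.integer())
  }
})

test_that("softmax outputs are probability vectors", {
  m <- build_res_bilstm(model_config(20, 3, 5, n_kernels = 4, lstm_units = 4),
                        seed = 2)
  x <- array(rnorm(7 * 20 * 3), c(7, 20, 3))
  p <- as.matrix(predict(m, x, type = "prob")[, 1:5])
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
})

test_that("inference is stateless: batches equal singles, repeats are bit-stable", {
  m <- build_res_bilstm(model_config(12, 2, 3, n_kernels = 4, lstm_units = 4,
                                     dropout = 0.5), seed = 3)
  x <- array(rnorm(4 * 12 * 2), c(4, 12, 2))
  batch <- as.matrix(predict(m, x, type = "prob")[, 1:3])
  singles <- t(vapply(1:4, function(i) {
    unlist(predict(m, x[i, , ], type = "prob")[, 1:3])
  }, numeric(3)))
  expect_equal(batch, singles, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(predict(m, x, type = "prob"), predict(m, x, type = "prob"))
})

test_that("window shape mismatches are rejected", {
  m <- build_res_bilstm(model_config(12, 2, 3, n_kernels = 4, lstm_units = 4),
                        seed = 3)
  expect_error(predict(m, array(0, c(2, 10, 2))), "12 x 2")
  expect_error(build_res_bilstm(model_config(3, 1, 2, kernel_size = 4)),
               "too short")
})

test_that("an untrained model with a zeroed head is exactly uniform", {
  m <- build_res_bilstm(model_config(16, 3, 4, n_kernels = 4, lstm_units = 8),
                        seed = 5)
  m$params$dense_W[] <- 0
  m$params$dense_b[] <- 0
  x <- array(rnorm(50 * 16 * 3), c(50, 16, 3))
  p <- as.matrix(predict(m, x, type = "prob")[, 1:4])
  expect_equal(unname(colMeans(p)), rep(0.25, 4), tolerance = 1e-12)
  expect_true(all(abs(p - 0.25) < 1e-12))
})
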