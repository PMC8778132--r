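# Small fixture builders used across the test files.

make_recordings <- function(values, activity = "walking", subject = "s1",
                            recording = 1L, sample_rate = 50) {
  values <- as.matrix(values)
  colnames(values) <- paste0("ch", seq_len(ncol(values)))
  df <- data.frame(subject = subject, recording = recording,
                   activity = activity, values, check.names = FALSE)
  imu_recordings(df, channels = colnames(values), sample_rate = sample_rate)
}

# A windowed dataset with two linearly separable classes: class "a" windows
# fluctuate around +mu, class "b" around -mu.
make_separable_dataset <- function(n_per_class = 40, L = 20, C = 3,
                                   mu = 1, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    windows <- array(rnorm(n * L * C, sd = noise), c(n, L, C))
    windows[seq_len(n_per_class), , ] <-
      windows[seq_len(n_per_class), , ] + mu
    windows[n_per_class + seq_len(n_per_class), , ] <-
      windows[n_per_class + seq_len(n_per_class), , ] - mu
    structure(list(
      windows = windows,
      labels = factor(rep(c("a", "b"), each = n_per_class)),
      window_length = L,
      channels = paste0("ch", seq_len(C)),
      class_levels = c("a", "b"),
      provenance = tibble::tibble(subject = "s1", recording = 1L,
                                  start = seq_len(n))
    ), class = "windowed_dataset")
  })
}

random_lstm_instance <- function(units, input_dim, steps, sd = 0.5) {
  list(
    Wx = matrix(rnorm(input_dim * 4 * units, sd = sd), input_dim, 4 * units),
    Wh = matrix(rnorm(units * 4 * units, sd = sd), units, 4 * units),
    b = rnorm(4 * units, sd = sd),
    X = array(rnorm(steps * input_dim), c(1, steps, input_dim))
  )
}

# Map the packed (D x 4H) batched parameterization onto the per-gate
# reference cell. Gate order along the 4H axis: input, forget, candidate,
# output.
packed_to_cell <- function(Wx, Wh, b) {
  H <- ncol(Wh) / 4
  D <- nrow(Wx)
  gi <- seq_len(H); gf <- H + gi; gc <- 2 * H + gi; go <- 3 * H + gi
  lstm_cell_params(H, D,
    U_i = t(Wx[, gi, drop = FALSE]), U_f = t(Wx[, gf, drop = FALSE]),
    U_c = t(Wx[, gc, drop = FALSE]), U_o = t(Wx[, go, drop = FALSE]),
    W_i = t(Wh[, gi, drop = FALSE]), W_f = t(Wh[, gf, drop = FALSE]),
    W_c = t(Wh[, gc, drop = FALSE]), W_o = t(Wh[, go, drop = FALSE]),
    b_i = b[gi], b_f = b[gf], b_c = b[gc], b_o = b[go])
}
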