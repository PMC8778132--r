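test_that("a zero-weight LSTM cell gives half-open gates and zero output", {
  p <- lstm_cell_params(units = 3, input_dim = 2)
  st <- lstm_step(p, c(5, -7))
  expect_equal(st$h, rep(0, 3))
  expect_equal(st$c, rep(0, 3))
  # the gates themselves: sigma(0) = 0.5, so with c_prev = 1 the cell halves
  st2 <- lstm_step(p, c(1, 1), state = list(h = rep(0, 3), c = rep(1, 3)))
  expect_equal(st2$c, rep(0.5, 3))
})

test_that("saturated forget/output gates preserve and emit the cell state", {
  p <- lstm_cell_params(units = 2, input_dim = 1,
                        b_f = 10, b_i = -10, b_o = 10)
  st <- lstm_step(p, 0.3, state = list(h = rep(0, 2), c = rep(1, 2)))
  c_exp <- plogis(10) * 1 + plogis(-10) * tanh(0)
  expect_equal(st$c, rep(c_exp, 2), tolerance = 1e-12)
  expect_equal(st$h, rep(plogis(10) * tanh(c_exp), 2), tolerance = 1e-12)
  expect_equal(st$c, rep(0.99995, 2), tolerance = 1e-4)
  expect_equal(st$h, rep(0.76157, 2), tolerance = 1e-4)
})

test_that("the batched recurrence matches the reference cell step by step", {
  withr::local_seed(101)
  lstm_forward <- resbilstm:::lstm_forward
  worst <- 0
  for (i in 1:100) {
    H <- sample(2:6, 1); D <- sample(2:5, 1); T <- sample(3:20, 1)
    inst <- random_lstm_instance(H, D, T)
    batched <- lstm_forward(inst$X, inst$Wx, inst$Wh, inst$b)
    cell <- packed_to_cell(inst$Wx, inst$Wh, inst$b)
    st <- NULL
    for (t in seq_len(T)) st <- lstm_step(cell, inst$X[1, t, ], st)
    worst <- max(worst, max(abs(st$h - batched$h_last[1, ])))
  }
  expect_lt(worst, 1e-5)
})

test_that("lstm_step validates shapes", {
  p <- lstm_cell_params(units = 2, input_dim = 3)
  expect_error(lstm_step(p, c(1, 2)), "length")
  expect_error(lstm_step(p, c(1, 2, 3), state = list(h = 0, c = 0)), "units")
})

test_that("bilstm of a one-step sequence is two independent single steps", {
  withr::local_seed(5)
  f <- packed_to_cell(matrix(rnorm(12), 3, 4), matrix(rnorm(4), 1, 4), rnorm(4))
  b <- packed_to_cell(matrix(rnorm(12), 3, 4), matrix(rnorm(4), 1, 4), rnorm(4))
  x <- matrix(rnorm(3), 1, 3)
  out <- bilstm_sequence(f, b, x)
  expect_equal(out$final,
               c(lstm_step(f, x[1, ])$h, lstm_step(b, x[1, ])$h))
  expect_equal(dim(out$outputs), c(1L, 2L))
})

test_that("all-zero parameters give an all-zero bilstm output", {
  f <- lstm_cell_params(2, 3); b <- lstm_cell_params(2, 3)
  out <- bilstm_sequence(f, b, matrix(rnorm(12), 4, 3))
  expect_equal(out$outputs, matrix(0, 4, 4))
  expect_equal(out$final, rep(0, 4))
})

test_that("the backward direction equals the forward cell on the reversed sequence", {
  withr::local_seed(9)
  for (i in 1:10) {
    H <- sample(2:4, 1); D <- sample(2:4, 1); T <- sample(2:8, 1)
    inst <- random_lstm_instance(H, D, T)
    cell <- packed_to_cell(inst$Wx, inst$Wh, inst$b)
    zero <- lstm_cell_params(H, D)
    seqm <- matrix(inst$X[1, , ], T, D)
    bwd_out <- bilstm_sequence(zero, cell, seqm)$outputs[, H + seq_len(H), drop = FALSE]
    fwd_on_rev <- bilstm_sequence(cell, zero, seqm[rev(seq_len(T)), , drop = FALSE])
    expect_equal(bwd_out,
                 fwd_on_rev$outputs[rev(seq_len(T)), seq_len(H), drop = FALSE])
  }
})

test_that("bilstm rejects empty sequences and mismatched cells", {
  f <- lstm_cell_params(2, 3)
  expect_error(bilstm_sequence(f, f, matrix(numeric(0), 0, 3)), "at least one")
  expect_error(bilstm_sequence(f, lstm_cell_params(3, 3), matrix(0, 2, 3)),
               "share")
})
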