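#' Single LSTM cell step (reference implementation)
#'
#' A direct, unbatched transcription of the LSTM gate equations, kept
#' deliberately separate from the vectorized recurrence used for training so
#' the two can be cross-checked against each other. With input `x_t`,
#' previous state `(h, c)` and per-gate weights `U` (input), `W` (recurrent)
#' and bias `b`:
#'
#' \deqn{i_t = \sigma(U_i x_t + W_i h_{t-1} + b_i)}
#' \deqn{f_t = \sigma(U_f x_t + W_f h_{t-1} + b_f)}
#' \deqn{\tilde c_t = \tanh(U_c x_t + W_c h_{t-1} + b_c)}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t}
#' \deqn{o_t = \sigma(U_o x_t + W_o h_{t-1} + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#'
#' @param params An [lstm_cell_params()] object.
#' @param x_t Input vector at time t (length = input dimension).
#' @param state A list with elements `h` and `c` (each length = units);
#'   defaults to the all-zero initial state.
#'
#' @return A list with elements `h` and `c`, the updated state.
#' @examples
#' p <- lstm_cell_params(units = 2, input_dim = 3) # all-zero weights
#' st <- lstm_step(p, c(1, -1, 2))
#' st$h # zero: o = 0.5 but tanh(c) = 0
#' @export
lstm_step <- function(params, x_t, state = NULL) {
  stopifnot(inherits(params, "lstm_cell_params"))
  u <- params$units
  if (length(x_t) != params$input_dim) {
    stop("`x_t` has length ", length(x_t), ", expected ", params$input_dim,
         call. = FALSE)
  }
  if (is.null(state)) state <- list(h = numeric(u), c = numeric(u))
  if (length(state$h) != u || length(state$c) != u) {
    stop("state vectors must have length `units` = ", u, call. = FALSE)
  }
  h <- state$h; c_prev <- state$c
  i <- sigmoid(drop(params$U_i %*% x_t + params$W_i %*% h) + params$b_i)
  f <- sigmoid(drop(params$U_f %*% x_t + params$W_f %*% h) + params$b_f)
  ctilde <- tanh(drop(params$U_c %*% x_t + params$W_c %*% h) + params$b_c)
  c_new <- f * c_prev + i * ctilde
  o <- sigmoid(drop(params$U_o %*% x_t + params$W_o %*% h) + params$b_o)
  list(h = as.vector(o * tanh(c_new)), c = as.vector(c_new))
}

#' Per-gate LSTM cell parameters
#'
#' Container for one LSTM cell's weights: input weights `U_*`
#' (units x input_dim), recurrent weights `W_*` (units x units) and biases
#' `b_*` (length units) for the input (i), forget (f), candidate (c) and
#' output (o) gates. Omitted pieces default to zero, which makes hand-built
#' worked examples easy.
#'
#' @param units Number of LSTM units.
#' @param input_dim Dimension of the input vector.
#' @param ... Named weight overrides (`U_i`, `W_f`, `b_o`, ...).
#' @return An object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(units, input_dim, ...) {
  stopifnot(units >= 1, input_dim >= 1)
  p <- list(units = as.integer(units), input_dim = as.integer(input_dim))
  for (g in c("i", "f", "c", "o")) {
    p[[paste0("U_", g)]] <- matrix(0, units, input_dim)
    p[[paste0("W_", g)]] <- matrix(0, units, units)
    p[[paste0("b_", g)]] <- numeric(units)
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown parameter `", nm, "`", call. = FALSE)
    tmpl <- p[[nm]]
    val <- dots[[nm]]
    if (length(val) == 1) val <- array(val, dim = dim(tmpl) %||% length(tmpl))
    if (!identical(length(val), length(tmpl))) {
      stop("`", nm, "` has wrong size", call. = FALSE)
    }
    if (is.matrix(tmpl)) dim(val) <- dim(tmpl) else val <- as.vector(val)
    p[[nm]] <- val
  }
  structure(p, class = "lstm_cell_params")
}

#' Run a bidirectional LSTM over one sequence (reference implementation)
#'
#' Applies one forward cell over `t = 1..T` and one backward cell over
#' `t = T..1`, both from zero initial state, stepping with [lstm_step()].
#' Per-step outputs concatenate the two directions' hidden states aligned at
#' the same time index; the `final` output — what the classifier head of the
#' full model consumes — concatenates the forward state after step T with
#' the backward state after it has processed the whole sequence (i.e. its
#' state at original time 1).
#'
#' @param forward,backward [lstm_cell_params()] for the two directions; they
#'   must agree on `units` and `input_dim`.
#' @param sequence A T x D matrix (rows = time steps).
#' @return A list with `outputs` (T x 2*units matrix) and `final`
#'   (length 2*units vector).
#' @export
bilstm_sequence <- function(forward, backward, sequence) {
  stopifnot(inherits(forward, "lstm_cell_params"),
            inherits(backward, "lstm_cell_params"))
  sequence <- as.matrix(sequence)
  T <- nrow(sequence)
  if (T < 1) stop("`sequence` must contain at least one time step", call. = FALSE)
  if (forward$units != backward$units ||
      forward$input_dim != backward$input_dim) {
    stop("forward and backward cells must share units and input_dim", call. = FALSE)
  }
  if (ncol(sequence) != forward$input_dim) {
    stop("sequence feature dimension (", ncol(sequence),
         ") does not match input_dim (", forward$input_dim, ")", call. = FALSE)
  }
  u <- forward$units
  hf <- matrix(0, T, u); hb <- matrix(0, T, u)
  st <- NULL
  for (t in seq_len(T)) {
    st <- lstm_step(forward, sequence[t, ], st)
    hf[t, ] <- st$h
  }
  st <- NULL
  for (t in rev(seq_len(T))) {
    st <- lstm_step(backward, sequence[t, ], st)
    hb[t, ] <- st$h
  }
  list(outputs = cbind(hf, hb), final = c(hf[T, ], hb[1, ]))
}
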