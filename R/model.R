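#' Model configuration for the residual-CNN BiLSTM classifier
#'
#' @param window_length Window length L in samples (>= 2).
#' @param n_channels Number of sensor channels C (>= 1).
#' @param n_classes Number of activity classes K (>= 2).
#' @param n_kernels Convolution kernels per layer; default 32.
#' @param kernel_size Side of the square convolution kernel; default 2.
#' @param lstm_units LSTM units per direction; default 64.
#' @param dropout Dropout rate on the BiLSTM output, in `[0, 1)`; default 0.5.
#' @return A `model_config` list.
#' @export
model_config <- function(window_length, n_channels, n_classes,
                         n_kernels = 32, kernel_size = 2,
                         lstm_units = 64, dropout = 0.5) {
  stopifnot(window_length >= 2, n_channels >= 1, n_classes >= 2,
            n_kernels >= 1, kernel_size >= 1, lstm_units >= 1,
            dropout >= 0, dropout < 1)
  structure(list(
    window_length = as.integer(window_length),
    n_channels = as.integer(n_channels),
    n_classes = as.integer(n_classes),
    n_kernels = as.integer(n_kernels),
    kernel_size = as.integer(kernel_size),
    lstm_units = as.integer(lstm_units),
    dropout = dropout
  ), class = "model_config")
}

# Shapes after the residual block: the stride-2 same-padded convolutions
# halve (rounding up) both the time and the channel axes; the feature map
# is then read as a sequence of ceil(L/2) steps with ceil(C/2)*n_kernels
# features per step.
seq_stage_shape <- function(config) {
  T <- ceiling(config$window_length / 2)
  Wo <- ceiling(config$n_channels / 2)
  c(steps = T, features = Wo * config$n_kernels, map_width = Wo)
}

#' Build the residual-CNN BiLSTM classifier
#'
#' Constructs the layer chain: input (L x C x 1) -> 2-D convolution
#' (`n_kernels` kernels of `kernel_size` x `kernel_size`, stride 2, zero
#' padded "same") + batch norm + ReLU -> identical convolution with stride 1
#' + batch norm + ReLU -> plus a parallel shortcut convolution (stride 2,
#' "same") + batch norm -> elementwise addition and ReLU -> reshape of the
#' ceil(L/2) x ceil(C/2) x n_kernels feature map to a sequence of ceil(L/2)
#' steps with ceil(C/2)*n_kernels features -> bidirectional LSTM
#' (`lstm_units` per direction, final forward and backward hidden states
#' concatenated) -> dropout -> dense layer to `n_classes` -> softmax.
#'
#' Weights are Glorot-uniform initialized; LSTM forget-gate biases start
#' at 1, all other biases at 0; batch-norm scale/shift start at 1/0.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization (optional).
#' @return An object of class `res_bilstm` holding the parameters, the
#'   configuration and an architecture summary.
#' @examples
#' m <- build_res_bilstm(model_config(40, 3, 6), seed = 1)
#' count_parameters(m) # 71462
#' @export
build_res_bilstm <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  k <- config$kernel_size
  F <- config$n_kernels
  H <- config$lstm_units
  K <- config$n_classes
  shp <- seq_stage_shape(config)
  if (config$window_length < k || shp[["steps"]] < 1) {
    stop("window too short for a ", k, "x", k, " stride-2 convolution",
         call. = FALSE)
  }
  D <- shp[["features"]]

  init <- function() {
    lstm_wx <- function() {
      m <- glorot_uniform(c(D, 4 * H), D, 4 * H)
      dim(m) <- c(D, 4 * H); m
    }
    lstm_wh <- function() {
      m <- glorot_uniform(c(H, 4 * H), H, 4 * H)
      dim(m) <- c(H, 4 * H); m
    }
    lstm_b <- function() c(numeric(H), rep(1, H), numeric(2 * H)) # forget bias 1
    list(
      conv1_W = glorot_uniform(c(k, k, 1, F), k * k * 1, k * k * F),
      conv1_b = numeric(F),
      bn1_gamma = rep(1, F), bn1_beta = numeric(F),
      conv2_W = glorot_uniform(c(k, k, F, F), k * k * F, k * k * F),
      conv2_b = numeric(F),
      bn2_gamma = rep(1, F), bn2_beta = numeric(F),
      sc_W = glorot_uniform(c(k, k, 1, F), k * k * 1, k * k * F),
      sc_b = numeric(F),
      bnsc_gamma = rep(1, F), bnsc_beta = numeric(F),
      f_Wx = lstm_wx(), f_Wh = lstm_wh(), f_b = lstm_b(),
      b_Wx = lstm_wx(), b_Wh = lstm_wh(), b_b = lstm_b(),
      dense_W = {m <- glorot_uniform(c(2 * H, K), 2 * H, K); dim(m) <- c(2 * H, K); m},
      dense_b = numeric(K)
    )
  }
  params <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  running <- list(
    bn1_mean = numeric(F), bn1_var = rep(1, F),
    bn2_mean = numeric(F), bn2_var = rep(1, F),
    bnsc_mean = numeric(F), bnsc_var = rep(1, F)
  )
  structure(list(
    config = config,
    params = params,
    running = running,
    class_levels = NULL,
    trained = FALSE
  ), class = "res_bilstm")
}

#' Architecture summary: layers, output shapes, trainable parameters
#'
#' @param x A `res_bilstm` model or a [model_config()].
#' @return A tibble with columns `layer`, `kind`, `output_shape` and
#'   `params` (trainable parameters; batch-norm running statistics are not
#'   trainable and are excluded).
#' @export
architecture_summary <- function(x) {
  config <- if (inherits(x, "res_bilstm")) x$config else x
  stopifnot(inherits(config, "model_config"))
  k <- config$kernel_size; F <- config$n_kernels; H <- config$lstm_units
  K <- config$n_classes; L <- config$window_length; C <- config$n_channels
  shp <- seq_stage_shape(config)
  T <- shp[["steps"]]; Wo <- shp[["map_width"]]; D <- shp[["features"]]
  conv_in1 <- k * k * 1 * F + F
  conv_ff <- k * k * F * F + F
  lstm_dir <- 4 * ((D + H) * H + H)
  shape_map <- sprintf("(%d, %d, %d)", T, Wo, F)
  tibble::tibble(
    layer = c("input", "conv_a", "bn_a", "relu_a", "conv_b", "bn_b", "relu_b",
              "shortcut_conv", "shortcut_bn", "add", "relu_out", "reshape",
              "bilstm", "dropout", "dense", "softmax"),
    kind = c("input", "conv2d s2 same", "batchnorm", "relu", "conv2d s1 same",
             "batchnorm", "relu", "conv2d s2 same", "batchnorm", "add", "relu",
             "reshape", "bilstm", "dropout", "dense", "softmax"),
    output_shape = c(sprintf("(%d, %d, 1)", L, C),
                     shape_map, shape_map, shape_map,
                     shape_map, shape_map, shape_map,
                     shape_map, shape_map, shape_map, shape_map,
                     sprintf("(%d, %d)", T, D),
                     sprintf("(%d)", 2 * H), sprintf("(%d)", 2 * H),
                     sprintf("(%d)", K), sprintf("(%d)", K)),
    params = c(0L, conv_in1, 2L * F, 0L, conv_ff, 2L * F, 0L,
               conv_in1, 2L * F, 0L, 0L, 0L,
               2L * lstm_dir, 0L, 2L * H * K + K, 0L)
  )
}

#' Count trainable parameters
#'
#' For a fitted or freshly built model the count is taken from the actual
#' parameter arrays; for a configuration or architecture summary it is the
#' sum of the per-layer counts. The two routes agree by construction and are
#' cross-checked in the test suite.
#'
#' @param x A `res_bilstm`, a [model_config()], or an
#'   [architecture_summary()] tibble.
#' @return Integer number of trainable parameters.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "res_bilstm")) {
    return(as.integer(sum(vapply(x$params, length, numeric(1)))))
  }
  if (inherits(x, "model_config")) x <- architecture_summary(x)
  stopifnot(is.data.frame(x), "params" %in% names(x))
  as.integer(sum(x$params))
}

# Full forward pass. x: (B, L, C) array. Returns logits and, when
# `training`, all caches needed for the backward pass.
model_forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
  p <- model$params; r <- model$running
  d <- dim(x)
  dim(x) <- c(d, 1)
  c1 <- conv2d_forward(x, p$conv1_W, p$conv1_b, stride = 2)
  b1 <- batchnorm_forward(c1$y, p$bn1_gamma, p$bn1_beta,
                          r$bn1_mean, r$bn1_var, training)
  r1 <- relu_forward(b1$y)
  c2 <- conv2d_forward(r1$y, p$conv2_W, p$conv2_b, stride = 1)
  b2 <- batchnorm_forward(c2$y, p$bn2_gamma, p$bn2_beta,
                          r$bn2_mean, r$bn2_var, training)
  r2 <- relu_forward(b2$y)
  cs <- conv2d_forward(x, p$sc_W, p$sc_b, stride = 2)
  bs <- batchnorm_forward(cs$y, p$bnsc_gamma, p$bnsc_beta,
                          r$bnsc_mean, r$bnsc_var, training)
  added <- r2$y + bs$y
  r3 <- relu_forward(added)
  md <- dim(r3$y)                       # (B, T, Wo, F)
  seq <- r3$y
  dim(seq) <- c(md[1], md[2], md[3] * md[4])
  fwd <- lstm_forward(seq, p$f_Wx, p$f_Wh, p$f_b)
  seq_rev <- seq[, rev(seq_len(md[2])), , drop = FALSE]
  bwd <- lstm_forward(seq_rev, p$b_Wx, p$b_Wh, p$b_b)
  hcat <- cbind(fwd$h_last, bwd$h_last)
  if (training && model$config$dropout > 0) {
    if (is.null(dropout_mask)) {
      keep <- 1 - model$config$dropout
      dropout_mask <- matrix(stats::rbinom(length(hcat), 1, keep) / keep,
                             nrow(hcat), ncol(hcat))
    }
    hdrop <- hcat * dropout_mask
  } else {
    hdrop <- hcat
  }
  logits <- hdrop %*% p$dense_W + matrix(p$dense_b, nrow(hdrop),
                                         length(p$dense_b), byrow = TRUE)
  list(logits = logits,
       cache = if (training) list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                                  r2 = r2, cs = cs, bs = bs, r3 = r3,
                                  fwd = fwd, bwd = bwd, hcat = hcat,
                                  hdrop = hdrop, dropout_mask = dropout_mask,
                                  map_dims = md) else NULL,
       running = if (training) list(
         bn1_mean = b1$running_mean, bn1_var = b1$running_var,
         bn2_mean = b2$running_mean, bn2_var = b2$running_var,
         bnsc_mean = bs$running_mean, bnsc_var = bs$running_var
       ) else NULL)
}

model_backward <- function(model, cache, dlogits) {
  p <- model$params
  md <- cache$map_dims
  grads <- list()
  grads$dense_W <- crossprod(cache$hdrop, dlogits)
  grads$dense_b <- colSums(dlogits)
  dhdrop <- dlogits %*% t(p$dense_W)
  dhcat <- if (!is.null(cache$dropout_mask)) dhdrop * cache$dropout_mask else dhdrop
  H <- model$config$lstm_units
  dfwd <- lstm_backward(dhcat[, seq_len(H), drop = FALSE], p$f_Wx, p$f_Wh, cache$fwd)
  dbwd <- lstm_backward(dhcat[, H + seq_len(H), drop = FALSE], p$b_Wx, p$b_Wh, cache$bwd)
  grads$f_Wx <- dfwd$dWx; grads$f_Wh <- dfwd$dWh; grads$f_b <- dfwd$db
  grads$b_Wx <- dbwd$dWx; grads$b_Wh <- dbwd$dWh; grads$b_b <- dbwd$db
  dseq <- dfwd$dX + dbwd$dX[, rev(seq_len(md[2])), , drop = FALSE]
  dmap <- dseq
  dim(dmap) <- md
  dadd <- relu_backward(dmap, cache$r3$mask)
  # residual split: gradient flows into both the stacked path and shortcut
  dr2 <- relu_backward(dadd, cache$r2$mask)
  db2 <- batchnorm_backward(dr2, cache$b2$cache)
  grads$bn2_gamma <- db2$dgamma; grads$bn2_beta <- db2$dbeta
  dc2 <- conv2d_backward(db2$dx, p$conv2_W, cache$c2$cache, need_dx = TRUE)
  grads$conv2_W <- dc2$dW; grads$conv2_b <- dc2$db
  dr1 <- relu_backward(dc2$dx, cache$r1$mask)
  db1 <- batchnorm_backward(dr1, cache$b1$cache)
  grads$bn1_gamma <- db1$dgamma; grads$bn1_beta <- db1$dbeta
  dc1 <- conv2d_backward(db1$dx, p$conv1_W, cache$c1$cache, need_dx = FALSE)
  grads$conv1_W <- dc1$dW; grads$conv1_b <- dc1$db
  dbs <- batchnorm_backward(dadd, cache$bs$cache)
  grads$bnsc_gamma <- dbs$dgamma; grads$bnsc_beta <- dbs$dbeta
  dcs <- conv2d_backward(dbs$dx, p$sc_W, cache$cs$cache, need_dx = FALSE)
  grads$sc_W <- dcs$dW; grads$sc_b <- dcs$db
  grads
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate; default 3e-4.
#' @param batch_size Minibatch size; default 64.
#' @param epochs Number of passes over the training split; default 80.
#' @param seed Integer seed controlling the train/validation split, weight
#'   initialization, minibatch shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 64,
                         epochs = 80, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the residual-CNN BiLSTM classifier
#'
#' Minimizes the categorical cross-entropy with Adam (moment decay 0.9 /
#' 0.999). The windowed dataset is split at window level into training and
#' validation subsets by a seeded shuffle; every class must appear in the
#' training split. Batch-norm uses batch statistics while training and its
#' running averages (momentum 0.9) at evaluation; dropout is active only
#' during training. Given the same seed the run is fully deterministic.
#'
#' @param model A `res_bilstm` from [build_res_bilstm()], or a
#'   [model_config()] (then a model is built with the training seed).
#' @param dataset A `windowed_dataset` from [segment_windows()].
#' @param config A [train_config()].
#' @param validation_split Fraction of windows held out for validation;
#'   default 0.3.
#' @param validation_indices Optional explicit validation window indices
#'   (e.g. all windows of held-out subjects), overriding the random split.
#' @param verbose Print one line per epoch.
#' @return A `res_bilstm_fit`: the trained model plus a `history` tibble
#'   with per-epoch `loss`, `val_loss`, `accuracy`, `val_accuracy`.
#' @export
fit_res_bilstm <- function(model, dataset, config = train_config(),
                           validation_split = 0.3,
                           validation_indices = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "windowed_dataset"), inherits(config, "train_config"))
  if (inherits(model, "model_config")) {
    model <- build_res_bilstm(model, seed = config$seed)
  }
  stopifnot(inherits(model, "res_bilstm"))
  n <- dim(dataset$windows)[1]
  if (n == 0) stop("empty dataset", call. = FALSE)
  y <- as.integer(dataset$labels)
  levels <- dataset$class_levels
  if (length(levels) != model$config$n_classes) {
    stop("dataset has ", length(levels), " classes but the model expects ",
         model$config$n_classes, call. = FALSE)
  }

  withr::local_seed(config$seed)
  if (is.null(validation_indices)) {
    perm <- sample.int(n)
    n_val <- floor(n * validation_split)
    val_idx <- perm[seq_len(n_val)]
    train_idx <- perm[-seq_len(n_val)]
  } else {
    val_idx <- validation_indices
    train_idx <- setdiff(seq_len(n), val_idx)
  }
  absent <- setdiff(seq_along(levels), unique(y[train_idx]))
  if (length(absent) > 0) {
    stop("class(es) missing from the training split: ",
         paste(levels[absent], collapse = ", "), call. = FALSE)
  }

  opt <- adam_init(model$params)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order <- sample(train_idx)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    tot_loss <- 0; tot_correct <- 0
    for (b in batches) {
      xb <- dataset$windows[b, , , drop = FALSE]
      fwd <- model_forward(model, xb, training = TRUE)
      model$running <- fwd$running
      sm <- softmax_xent(fwd$logits, y[b])
      grads <- model_backward(model, fwd$cache, sm$dlogits)
      upd <- adam_update(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      tot_loss <- tot_loss + sm$loss * length(b)
      tot_correct <- tot_correct + sum(max.col(sm$probs) == y[b])
    }
    ev <- evaluate_split(model, dataset$windows, y, val_idx)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch,
      loss = tot_loss / length(train_idx),
      accuracy = tot_correct / length(train_idx),
      val_loss = ev$loss,
      val_accuracy = ev$accuracy
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f",
                      epoch, hist[[epoch]]$loss, hist[[epoch]]$accuracy,
                      ev$loss, ev$accuracy))
    }
  }
  model$trained <- TRUE
  model$class_levels <- levels
  structure(list(
    model = model,
    history = dplyr::bind_rows(hist),
    train_indices = train_idx,
    val_indices = val_idx,
    config = config
  ), class = "res_bilstm_fit")
}

evaluate_split <- function(model, windows, y, idx, batch_size = 256L) {
  if (length(idx) == 0) return(list(loss = NA_real_, accuracy = NA_real_))
  tot_loss <- 0; tot_correct <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    xb <- windows[b, , , drop = FALSE]
    fwd <- model_forward(model, xb, training = FALSE)
    sm <- softmax_xent(fwd$logits, y[b])
    tot_loss <- tot_loss + sm$loss * length(b)
    tot_correct <- tot_correct + sum(max.col(sm$probs) == y[b])
  }
  list(loss = tot_loss / length(idx), accuracy = tot_correct / length(idx))
}

#' Predict activity classes for windows
#'
#' Runs the model in inference mode (dropout off, batch-norm running
#' statistics), so repeated calls on the same input are bit-identical.
#'
#' @param object A `res_bilstm_fit` (or bare `res_bilstm`).
#' @param new_data A `windowed_dataset` or an `n x L x C` array (a single
#'   `L x C` matrix is treated as one window).
#' @param type `"prob"` for a tibble of class probabilities, `"class"` for
#'   predicted labels.
#' @param ... Unused.
#' @return A tibble of per-class probabilities plus a `.pred_class` column,
#'   or a factor of predicted classes.
#' @export
predict.res_bilstm_fit <- function(object, new_data, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  model <- object$model
  res <- predict_probs(model, new_data)
  if (type == "class") return(res$class)
  out <- tibble::as_tibble(as.data.frame(res$probs))
  names(out) <- paste0(".pred_", res$levels)
  out$.pred_class <- res$class
  out
}

#' @export
predict.res_bilstm <- function(object, new_data, type = c("prob", "class"), ...) {
  predict.res_bilstm_fit(list(model = object), new_data, type, ...)
}

predict_probs <- function(model, new_data, batch_size = 256L) {
  levels <- model$class_levels %||% as.character(seq_len(model$config$n_classes))
  if (inherits(new_data, "windowed_dataset")) new_data <- new_data$windows
  if (is.matrix(new_data)) {
    new_data <- array(new_data, dim = c(1, dim(new_data)))
  }
  d <- dim(new_data)
  if (length(d) != 3 || d[2] != model$config$window_length ||
      d[3] != model$config$n_channels) {
    stop("windows must be n x ", model$config$window_length, " x ",
         model$config$n_channels, call. = FALSE)
  }
  probs <- matrix(0, d[1], model$config$n_classes)
  for (b in split(seq_len(d[1]), ceiling(seq_len(d[1]) / batch_size))) {
    fwd <- model_forward(model, new_data[b, , , drop = FALSE], training = FALSE)
    probs[b, ] <- softmax_rows(fwd$logits)
  }
  list(probs = probs,
       class = factor(levels[max.col(probs)], levels = levels),
       levels = levels)
}

#' @export
print.res_bilstm <- function(x, ...) {
  cat("Residual-CNN BiLSTM classifier\n")
  cat(sprintf("  window %d x %d, %d classes, %s trainable parameters\n",
              x$config$window_length, x$config$n_channels,
              x$config$n_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.res_bilstm_fit <- function(x, ...) {
  print(x$model)
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epochs; final val accuracy %.4f (val loss %.4f)\n",
              nrow(x$history), h$val_accuracy, h$val_loss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.res_bilstm_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' @export
glance.res_bilstm_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    parameters = count_parameters(x$model),
    loss = h$loss, accuracy = h$accuracy,
    val_loss = h$val_loss, val_accuracy = h$val_accuracy
  )
}
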