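# Low-level numerical layers: zero-padded 2-D convolution, batch
# normalization, batched LSTM, dense head, softmax cross-entropy and Adam.
# All activations are plain R arrays in (batch, height, width, channel)
# order; the heavy lifting is matrix multiplication so BLAS does the work.
# These are internal; the user-facing model lives in model.R.

sigmoid <- function(x) 1 / (1 + exp(-x))

flat2 <- function(x) {
  # view a (B, H, W, C) array as a (B*H*W, C) matrix (C is the last axis)
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

# "same" padding sizes for one axis (TensorFlow convention: the extra
# padding row/column, when odd, goes after the data)
same_pad <- function(n, k, stride) {
  out <- ceiling(n / stride)
  total <- max((out - 1L) * stride + k - n, 0L)
  c(before = total %/% 2L, after = total - total %/% 2L, out = out)
}

conv2d_forward <- function(x, W, b, stride) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  ph <- same_pad(H, kh, stride); pw <- same_pad(Wd, kw, stride)
  Ho <- ph[["out"]]; Wo <- pw[["out"]]
  if (Ho < 1 || Wo < 1) stop("input too small for this convolution", call. = FALSE)
  xp <- array(0, dim = c(B, H + ph[["before"]] + ph[["after"]],
                         Wd + pw[["before"]] + pw[["after"]], Cin))
  xp[, ph[["before"]] + seq_len(H), pw[["before"]] + seq_len(Wd), ] <- x
  out <- matrix(b, nrow = B * Ho * Wo, ncol = Cout, byrow = TRUE)
  for (di in seq_len(kh)) {
    r <- (seq_len(Ho) - 1L) * stride + di
    for (dj in seq_len(kw)) {
      cc <- (seq_len(Wo) - 1L) * stride + dj
      xs <- xp[, r, cc, , drop = FALSE]
      dim(xs) <- c(B * Ho * Wo, Cin)
      out <- out + xs %*% matrix(W[di, dj, , ], Cin, Cout)
    }
  }
  dim(out) <- c(B, Ho, Wo, Cout)
  list(y = out, cache = list(xp = xp, dims = d, stride = stride,
                             ph = ph, pw = pw, kh = kh, kw = kw))
}

conv2d_backward <- function(dy, W, cache, need_dx = TRUE) {
  d <- cache$dims
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- cache$kh; kw <- cache$kw
  Cout <- dim(W)[4]
  Ho <- dim(dy)[2]; Wo <- dim(dy)[3]
  D <- dy; dim(D) <- c(B * Ho * Wo, Cout)
  dW <- array(0, dim = dim(W))
  db <- colSums(D)
  dxp <- if (need_dx) array(0, dim = dim(cache$xp)) else NULL
  for (di in seq_len(kh)) {
    r <- (seq_len(Ho) - 1L) * cache$stride + di
    for (dj in seq_len(kw)) {
      cc <- (seq_len(Wo) - 1L) * cache$stride + dj
      xs <- cache$xp[, r, cc, , drop = FALSE]
      dim(xs) <- c(B * Ho * Wo, Cin)
      dW[di, dj, , ] <- crossprod(xs, D)
      if (need_dx) {
        contrib <- D %*% t(matrix(W[di, dj, , ], Cin, Cout))
        dim(contrib) <- c(B, Ho, Wo, Cin)
        dxp[, r, cc, ] <- dxp[, r, cc, , drop = FALSE] + contrib
      }
    }
  }
  dx <- NULL
  if (need_dx) {
    dx <- dxp[, cache$ph[["before"]] + seq_len(H),
              cache$pw[["before"]] + seq_len(Wd), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

batchnorm_forward <- function(x, gamma, beta, running_mean, running_var,
                              training, momentum = 0.9, eps = 1e-5) {
  d <- dim(x)
  m <- flat2(x)
  N <- nrow(m); C <- ncol(m)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu  # population variance over batch+space
    running_mean <- momentum * running_mean + (1 - momentum) * mu
    running_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - matrix(mu, N, C, byrow = TRUE)) * matrix(inv, N, C, byrow = TRUE)
  y <- xhat * matrix(gamma, N, C, byrow = TRUE) + matrix(beta, N, C, byrow = TRUE)
  dim(y) <- d
  list(y = y, running_mean = running_mean, running_var = running_var,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d))
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$dims
  dm <- dy; dim(dm) <- dim(cache$xhat)
  N <- nrow(dm); C <- ncol(dm)
  xhat <- cache$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- dm * matrix(cache$gamma, N, C, byrow = TRUE)
  dx <- (dxhat -
           matrix(colMeans(dxhat), N, C, byrow = TRUE) -
           xhat * matrix(colMeans(dxhat * xhat), N, C, byrow = TRUE)) *
    matrix(cache$inv, N, C, byrow = TRUE)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, mask) dy * mask

# Batched LSTM over a (B, T, D) sequence. Gate order along the 4H axis is
# input, forget, candidate, output. Only the final hidden state feeds the
# classifier, so the backward pass injects an external gradient at step T
# and lets it flow back through the recurrence.
lstm_forward <- function(X, Wx, Wh, b) {
  d <- dim(X)
  B <- d[1]; T <- d[2]; D <- d[3]
  H <- ncol(Wh) / 4
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2 * H + idx_i; idx_o <- 3 * H + idx_i
  caches <- vector("list", T)
  for (t in seq_len(T)) {
    Xt <- matrix(X[, t, ], B, D)
    Z <- Xt %*% Wx + h %*% Wh + bmat
    i <- sigmoid(Z[, idx_i, drop = FALSE])
    f <- sigmoid(Z[, idx_f, drop = FALSE])
    g <- tanh(Z[, idx_g, drop = FALSE])
    o <- sigmoid(Z[, idx_o, drop = FALSE])
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[t]] <- list(Xt = Xt, h_prev = h, c_prev = c,
                        i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; c <- c_new
  }
  list(h_last = h, caches = caches, dims = d, H = H)
}

lstm_backward <- function(dh_last, Wx, Wh, fwd) {
  d <- fwd$dims
  B <- d[1]; T <- d[2]; D <- d[3]; H <- fwd$H
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dX <- array(0, dim = d)
  dh <- dh_last
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    cc <- fwd$caches[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$Xt, dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(Wx)
    dh <- dZ %*% t(Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its gradient w.r.t. the logits
softmax_xent <- function(logits, y_index) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y_index)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y_index)] <- dlogits[cbind(seq_len(n), y_index)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
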