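# Compact CNN-LSTM sequence classifier for 40-frame streams of 8x8
# thermal images, implemented from scratch in base R: three 3x3
# convolutional layers (same padding, ReLU, no pooling - the frames are
# tiny) applied identically to every frame, the flattened per-frame
# feature maps fed to two stacked LSTM layers, and a softmax head read
# from the final hidden state. Trained with Adam on the cross-entropy
# loss via backpropagation through time. The study configuration is 16/32/32
# filters, two 32-unit LSTM layers, 1000 epochs, batch size 32; the epoch
# budget is freely reducible for desk-scale runs.

#' CNN-LSTM network configuration
#'
#' @param filters convolutional filter counts (default `c(16, 32, 32)`).
#' @param kernel square kernel size (default 3).
#' @param lstm_units units of the two stacked LSTM layers (default
#'   `c(32, 32)`).
#' @param epochs training epochs (study default 1000; reduce freely for
#'   small runs).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return an object of class `net_config`.
#' @export
net_config <- function(filters = c(16L, 32L, 32L), kernel = 3L,
                       lstm_units = c(32L, 32L), epochs = 1000L,
                       batch_size = 32L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(filters) == 3, all(filters > 0), kernel == 3L,
            length(lstm_units) == 2, all(lstm_units > 0),
            epochs > 0, batch_size > 0, learning_rate > 0)
  structure(list(filters = as.integer(filters), kernel = 3L,
                 lstm_units = as.integer(lstm_units),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "net_config")
}

# 3x3 same-padding neighbor index table for an 8x8 grid flattened
# row-major: idx[p, k] is the input pixel feeding tap k of output pixel p
# (NA = zero padding).
conv_index_table <- function() {
  idx <- matrix(NA_integer_, 64L, 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    for (r in 1:8) for (c in 1:8) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 8 && cc >= 1 && cc <= 8)
        idx[8L * (r - 1L) + c, k] <- 8L * (rr - 1L) + cc
    }
  }
  idx
}

# X: (F, 64, C) array -> (F*64) x (9*C) patch matrix.
im2col <- function(X, idx) {
  Fn <- dim(X)[1]; C <- dim(X)[3]
  out <- matrix(0, Fn * 64L, 9L * C)
  for (k in 1:9) {
    ok <- !is.na(idx[, k])
    block <- array(0, c(Fn, 64L, C))
    block[, ok, ] <- X[, idx[ok, k], , drop = FALSE]
    out[, ((k - 1L) * C + 1L):(k * C)] <- matrix(block, Fn * 64L, C)
  }
  out
}

# Scatter-add gradient of im2col back to the input array.
col2im <- function(dcol, idx, Fn, C) {
  dX <- array(0, c(Fn, 64L, C))
  for (k in 1:9) {
    ok <- which(!is.na(idx[, k]))
    blk <- array(dcol[, ((k - 1L) * C + 1L):(k * C)], c(Fn, 64L, C))
    for (p in ok)
      dX[, idx[p, k], ] <- dX[, idx[p, k], ] + blk[, p, ]
  }
  dX
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained CNN-LSTM model
#'
#' @param config a [net_config()].
#' @param n_classes number of activity classes (>= 2).
#' @return an object of class `cnn_lstm` holding the parameter set.
#' @export
build_model <- function(config, n_classes) {
  if (!inherits(config, "net_config")) stop("config must be a net_config")
  if (n_classes < 2) stop("need at least 2 classes")
  f <- config$filters; H <- config$lstm_units
  din <- 64L * f[3]
  with_seed(config$seed, {
    par <- list(
      W1 = glorot(9L * 1L, f[1]),   b1 = numeric(f[1]),
      W2 = glorot(9L * f[1], f[2]), b2 = numeric(f[2]),
      W3 = glorot(9L * f[2], f[3]), b3 = numeric(f[3]),
      Wx1 = glorot(din, 4L * H[1]), Wh1 = glorot(H[1], 4L * H[1]),
      bl1 = rep(c(0, 1, 0, 0), each = H[1]),  # forget-gate bias 1
      Wx2 = glorot(H[1], 4L * H[2]), Wh2 = glorot(H[2], 4L * H[2]),
      bl2 = rep(c(0, 1, 0, 0), each = H[2]),
      Wd = glorot(H[2], n_classes), bd = numeric(n_classes))
    structure(list(par = par, config = config, n_classes = n_classes,
                   classes = NULL, idx = conv_index_table(),
                   norm = list(mean = 0, sd = 1)),
              class = "cnn_lstm")
  })
}

#' @export
print.cnn_lstm <- function(x, ...) {
  f <- x$config$filters; H <- x$config$lstm_units
  cat("<cnn_lstm> conv", paste(f, collapse = "/"), "(3x3, same, ReLU) -> LSTM",
      paste(H, collapse = "/"), "->", x$n_classes, "classes",
      if (is.null(x$classes)) "(untrained)" else "(trained)", "\n")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM layer forward over T steps. xs: list of T matrices (B x Din).
lstm_forward <- function(xs, Wx, Wh, b, H) {
  B <- nrow(xs[[1]]); Tn <- length(xs)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", Tn); hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- xs[[t]] %*% Wx + h %*% Wh + matrix(b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev_cache <- h
    h <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                       tc = tc, h_prev = h_prev_cache, x = xs[[t]])
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# Backprop through an LSTM layer. dhs: list of upstream dh per step (may be
# zeros except the last). Returns parameter grads and per-step dx.
lstm_backward <- function(dhs, cache, Wx, Wh, H) {
  Tn <- length(cache); B <- nrow(dhs[[Tn]])
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dxs <- vector("list", Tn)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in Tn:1) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    do_ <- dh * cc$tc * cc$o * (1 - cc$o)
    da <- cbind(di, df, dg, do_)
    dWx <- dWx + crossprod(cc$x, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dxs[[t]] <- da %*% t(Wx)
    dh_next <- da %*% t(Wh)
    dc_next <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

# Full forward pass. samples: (B, T, 8, 8) array (already standardized).
# Returns probabilities and, when keep = TRUE, the caches for backprop.
net_forward <- function(model, samples, keep = FALSE) {
  par <- model$par; idx <- model$idx
  B <- dim(samples)[1]; Tn <- dim(samples)[2]
  f <- model$config$filters; H <- model$config$lstm_units
  # frames as (B*T, 64, 1): frame (b, t) is row b + (t-1)*B, pixels reordered
  # from the array's column-major flattening to the package's row-major order
  perm <- as.vector(t(matrix(1:64, 8, 8)))
  X0 <- array(matrix(samples, B * Tn, 64)[, perm], c(B * Tn, 64, 1))
  c1 <- im2col(X0, idx); z1 <- sweep(c1 %*% par$W1, 2, par$b1, "+"); a1 <- pmax(z1, 0)
  A1 <- array(a1, c(B * Tn, 64, f[1]))
  c2 <- im2col(A1, idx); z2 <- sweep(c2 %*% par$W2, 2, par$b2, "+"); a2 <- pmax(z2, 0)
  A2 <- array(a2, c(B * Tn, 64, f[2]))
  c3 <- im2col(A2, idx); z3 <- sweep(c3 %*% par$W3, 2, par$b3, "+"); a3 <- pmax(z3, 0)
  feat <- matrix(a3, B * Tn, 64 * f[3])  # (b,t)-row-major flatten of (64, C)
  xs <- lapply(seq_len(Tn), function(t) feat[(t - 1L) * B + seq_len(B), , drop = FALSE])
  l1 <- lstm_forward(xs, par$Wx1, par$Wh1, par$bl1, H[1])
  l2 <- lstm_forward(l1$hs, par$Wx2, par$Wh2, par$bl2, H[2])
  logits <- sweep(l2$hs[[Tn]] %*% par$Wd, 2, par$bd, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (!keep) return(list(probs = probs))
  list(probs = probs, caches = list(c1 = c1, z1 = z1, c2 = c2, z2 = z2,
                                    c3 = c3, z3 = z3, l1 = l1, l2 = l2,
                                    B = B, Tn = Tn))
}

# Gradients of mean cross-entropy wrt all parameters.
net_backward <- function(model, caches, probs, y_onehot) {
  par <- model$par; idx <- model$idx
  B <- caches$B; Tn <- caches$Tn
  f <- model$config$filters; H <- model$config$lstm_units
  dlogits <- (probs - y_onehot) / B
  h2T <- caches$l2$hs[[Tn]]
  g <- list(Wd = crossprod(h2T, dlogits), bd = colSums(dlogits))
  zero2 <- matrix(0, B, H[2])
  dhs2 <- c(rep(list(zero2), Tn - 1), list(dlogits %*% t(par$Wd)))
  b2g <- lstm_backward(dhs2, caches$l2$cache, par$Wx2, par$Wh2, H[2])
  g$Wx2 <- b2g$dWx; g$Wh2 <- b2g$dWh; g$bl2 <- b2g$db
  b1g <- lstm_backward(b2g$dxs, caches$l1$cache, par$Wx1, par$Wh1, H[1])
  g$Wx1 <- b1g$dWx; g$Wh1 <- b1g$dWh; g$bl1 <- b1g$db
  dfeat <- matrix(0, B * Tn, 64L * f[3])
  for (t in seq_len(Tn)) dfeat[(t - 1L) * B + seq_len(B), ] <- b1g$dxs[[t]]
  da3 <- matrix(dfeat, B * Tn * 64L, f[3])
  dz3 <- da3 * (caches$z3 > 0)
  g$W3 <- crossprod(caches$c3, dz3); g$b3 <- colSums(dz3)
  dA2 <- col2im(dz3 %*% t(par$W3), idx, B * Tn, f[2])
  dz2 <- matrix(dA2, B * Tn * 64L, f[2]) * (caches$z2 > 0)
  g$W2 <- crossprod(caches$c2, dz2); g$b2 <- colSums(dz2)
  dA1 <- col2im(dz2 %*% t(par$W2), idx, B * Tn, f[1])
  dz1 <- matrix(dA1, B * Tn * 64L, f[1]) * (caches$z1 > 0)
  g$W1 <- crossprod(caches$c1, dz1); g$b1 <- colSums(dz1)
  g
}

# Convert a dataset tensor or (Z, 40, 64) array into the (Z, T, 8, 8)
# sequence array expected by the network.
#' Reshape spatiotemporal maps back into frame sequences
#'
#' @param data a [dataset_tensor()].
#' @return array of dimension Z x 40 x 8 x 8 (row-major pixel unflattening).
#' @export
tensor_to_sequences <- function(data) {
  Z <- n_samples(data); Tn <- dim(data$maps)[2]
  out <- array(0, c(Z, Tn, 8, 8))
  for (i in seq_len(Z)) for (t in seq_len(Tn))
    out[i, t, , ] <- vector_to_frame(data$maps[i, t, ])
  out
}

#' Train a CNN-LSTM model
#'
#' Standardizes the frames with the training-set mean and standard
#' deviation, then runs minibatch Adam on the cross-entropy loss.
#' Deterministic on one CPU given the configuration seed.
#'
#' @param model an untrained (or previously trained) [build_model()] output.
#' @param samples array Z x T x 8 x 8 of frame sequences, or a
#'   [dataset_tensor()] (converted via [tensor_to_sequences()]).
#' @param labels activity code per sequence (taken from the tensor when
#'   `samples` is a [dataset_tensor()]).
#' @param epochs optional override of the configured epoch count.
#' @return the fitted model, with the per-epoch mean training loss in
#'   `$loss_curve`.
#' @export
train_model <- function(model, samples, labels = NULL, epochs = NULL) {
  if (inherits(samples, "dataset_tensor")) {
    labels <- samples$labels
    samples <- tensor_to_sequences(samples)
  }
  if (length(labels) == 0 || dim(samples)[1] == 0) stop("empty training set")
  if (dim(samples)[1] != length(labels)) stop("one label per sequence required")
  y <- factor(labels)
  if (nlevels(y) != model$n_classes)
    stop("model was built for ", model$n_classes, " classes, data has ", nlevels(y))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  mu <- mean(samples); sdv <- stats::sd(samples)
  if (sdv == 0) sdv <- 1
  model$norm <- list(mean = mu, sd = sdv)
  samples <- (samples - mu) / sdv
  Z <- dim(samples)[1]
  Yh <- diag(model$n_classes)[as.integer(y), , drop = FALSE]
  # Adam state
  ms <- lapply(model$par, function(p) p * 0)
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
  loss_curve <- numeric(epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(Z)
      losses <- c()
      for (start in seq(1, Z, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, Z)]
        fw <- net_forward(model, samples[bi, , , , drop = FALSE], keep = TRUE)
        p <- pmax(fw$probs, 1e-12)
        losses <- c(losses, -mean(log(p[cbind(seq_along(bi), as.integer(y)[bi])])))
        gr <- net_backward(model, fw$caches, fw$probs, Yh[bi, , drop = FALSE])
        step <- step + 1
        for (nm in names(model$par)) {
          ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * gr[[nm]]
          vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * gr[[nm]]^2
          mhat <- ms[[nm]] / (1 - beta1^step)
          vhat <- vs[[nm]] / (1 - beta2^step)
          model$par[[nm]] <- model$par[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_curve[ep] <- mean(losses)
    }
  })
  model$classes <- levels(y)
  model$loss_curve <- loss_curve
  model
}

#' Predict with a CNN-LSTM model
#'
#' @param model a trained `cnn_lstm`.
#' @param samples sequence array or [dataset_tensor()].
#' @param type `"class"` or `"prob"`.
#' @return labels, or a probability matrix with rows summing to 1.
#' @export
predict_model <- function(model, samples, type = c("class", "prob")) {
  type <- match.arg(type)
  if (inherits(samples, "dataset_tensor")) samples <- tensor_to_sequences(samples)
  samples <- (samples - model$norm$mean) / model$norm$sd
  probs <- net_forward(model, samples)$probs
  if (type == "prob") return(probs)
  cl <- model$classes %||% as.character(seq_len(model$n_classes))
  cl[max.col(probs, ties.method = "first")]
}

#' Evaluate a CNN-LSTM model on labelled sequences
#'
#' @param model a trained `cnn_lstm`.
#' @param samples sequence array or [dataset_tensor()].
#' @param labels reference labels (taken from the tensor when omitted).
#' @return list with `accuracy` and `confusion` (truth in rows).
#' @export
evaluate_model <- function(model, samples, labels = NULL) {
  if (inherits(samples, "dataset_tensor")) {
    labels <- samples$labels
  }
  if (is.null(labels) || length(labels) == 0) stop("empty test set")
  pred <- predict_model(model, samples)
  list(accuracy = accuracy_of(pred, labels),
       confusion = confusion_matrix(pred, labels, classes = model$classes))
}
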