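#' Configuration of the hybrid CNN + BiLSTM network
#'
#' Architecture and optimization settings: two 1-D convolutional layers
#' (32 filters of size 5, then 64 filters of size 3, ReLU, "same" padding so
#' the 61-window sequence survives), each followed by max pooling with stride
#' 2 (61 -> 30 -> 15), a bidirectional LSTM with 64 units per direction, a
#' 64-unit ReLU dense layer and a single sigmoid output. Training uses Adam
#' on binary cross-entropy with early stopping on a validation split.
#'
#' @param conv1_filters,conv1_kernel first convolution (default 32 filters,
#'   kernel 5).
#' @param conv2_filters,conv2_kernel second convolution (default 64 filters,
#'   kernel 3).
#' @param lstm_units LSTM units per direction (default 64).
#' @param dense_units hidden dense units (default 64).
#' @param batch_size mini-batch size; the default 16 sits inside the 6-20
#'   range the protocol prescribes.
#' @param max_epochs epoch budget (default 200).
#' @param patience early-stopping patience in epochs (default 10).
#' @param learning_rate Adam step size (default 1e-3).
#' @param val_fraction fraction of the training data held out for early
#'   stopping (default 0.15).
#' @param seed integer seed driving initialization, batching and oversampling.
#' @return An object of class `hnn_config`.
#' @export
hnn_config <- function(conv1_filters = 32, conv1_kernel = 5,
                       conv2_filters = 64, conv2_kernel = 3,
                       lstm_units = 64, dense_units = 64,
                       batch_size = 16, max_epochs = 200, patience = 10,
                       learning_rate = 1e-3, val_fraction = 0.15,
                       seed = 1) {
  stopifnot(conv1_filters >= 1, conv2_filters >= 1,
            conv1_kernel >= 1, conv2_kernel >= 1,
            lstm_units >= 1, dense_units >= 1, batch_size >= 1,
            max_epochs >= 1, learning_rate > 0,
            val_fraction > 0, val_fraction < 0.5)
  structure(
    list(conv1_filters = as.integer(conv1_filters),
         conv1_kernel = as.integer(conv1_kernel),
         conv2_filters = as.integer(conv2_filters),
         conv2_kernel = as.integer(conv2_kernel),
         lstm_units = as.integer(lstm_units),
         dense_units = as.integer(dense_units),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience),
         learning_rate = learning_rate,
         val_fraction = val_fraction,
         seed = as.integer(seed)),
    class = "hnn_config"
  )
}

glorot <- function(nin, nout, n_row, n_col) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(n_row * n_col, -lim, lim), n_row, n_col)
}

#' Build an untrained hybrid network
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases, LSTM
#' forget-gate bias 1) for the given input shape. The sequence length must be
#' at least 8 so that it survives both stride-2 poolings with usable length.
#'
#' @param input_shape integer pair `c(n_windows, n_features_per_window)`.
#' @param cfg an [hnn_config()].
#' @return An object of class `hnn_model` (untrained).
#' @export
build_hnn <- function(input_shape, cfg = hnn_config()) {
  stopifnot(length(input_shape) == 2)
  T_in <- as.integer(input_shape[1]); F_in <- as.integer(input_shape[2])
  if (T_in < 8) {
    stop(sprintf(
      "sequence length %d too short: need >= 8 to survive two stride-2 poolings",
      T_in
    ))
  }
  u <- cfg$lstm_units
  params <- with_local_seed(cfg$seed, {
    p <- list(
      W1 = glorot(cfg$conv1_kernel * F_in, cfg$conv1_filters,
                  cfg$conv1_kernel * F_in, cfg$conv1_filters),
      b1 = numeric(cfg$conv1_filters),
      W2 = glorot(cfg$conv2_kernel * cfg$conv1_filters, cfg$conv2_filters,
                  cfg$conv2_kernel * cfg$conv1_filters, cfg$conv2_filters),
      b2 = numeric(cfg$conv2_filters)
    )
    for (dir in c("f", "b")) {
      p[[paste0("Wx_", dir)]] <- glorot(cfg$conv2_filters + u, u,
                                        cfg$conv2_filters, 4 * u)
      p[[paste0("Wh_", dir)]] <- glorot(cfg$conv2_filters + u, u, u, 4 * u)
      bl <- numeric(4 * u)
      bl[(u + 1):(2 * u)] <- 1           # forget-gate bias
      p[[paste0("bl_", dir)]] <- bl
    }
    p$W3 <- glorot(2 * u, cfg$dense_units, 2 * u, cfg$dense_units)
    p$b3 <- numeric(cfg$dense_units)
    p$W4 <- glorot(cfg$dense_units, 1, cfg$dense_units, 1)
    p$b4 <- numeric(1)
    p
  })
  structure(
    list(params = params, cfg = cfg, input_shape = c(T_in, F_in),
         trained = FALSE, training_meta = NULL),
    class = "hnn_model"
  )
}

#' Number of trainable parameters of a hybrid network
#'
#' @param model an [build_hnn()] / trained `hnn_model`.
#' @return Integer parameter count.
#' @export
hnn_param_count <- function(model) {
  stopifnot(inherits(model, "hnn_model"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- layer primitives (batch-major arrays [B, T, F]) ----------------------

conv1d_same_forward <- function(X, W, b, kernel) {
  d <- dim(X); B <- d[1]; T_len <- d[2]; F_in <- d[3]
  p_l <- (kernel - 1L) %/% 2L
  Xp <- array(0, c(B, T_len + kernel - 1L, F_in))
  Xp[, (p_l + 1):(p_l + T_len), ] <- X
  M <- matrix(0, B * T_len, kernel * F_in)
  for (j in seq_len(kernel)) {
    Sj <- Xp[, j:(j + T_len - 1L), , drop = FALSE]
    dim(Sj) <- c(B * T_len, F_in)
    M[, ((j - 1L) * F_in + 1L):(j * F_in)] <- Sj
  }
  H <- M %*% W
  H <- H + matrix(b, nrow(H), length(b), byrow = TRUE)
  A <- pmax(H, 0)
  list(M = M, mask = H > 0, out = array(A, c(B, T_len, ncol(W))),
       kernel = kernel, F_in = F_in, B = B, T_len = T_len)
}

conv1d_same_backward <- function(cache, W, dOut) {
  B <- cache$B; T_len <- cache$T_len; F_in <- cache$F_in; k <- cache$kernel
  dH <- matrix(dOut, B * T_len, ncol(W)) * cache$mask
  dW <- crossprod(cache$M, dH)
  db <- colSums(dH)
  dM <- dH %*% t(W)
  p_l <- (k - 1L) %/% 2L
  dXp <- array(0, c(B, T_len + k - 1L, F_in))
  for (j in seq_len(k)) {
    dSj <- dM[, ((j - 1L) * F_in + 1L):(j * F_in), drop = FALSE]
    dim(dSj) <- c(B, T_len, F_in)
    dXp[, j:(j + T_len - 1L), ] <- dXp[, j:(j + T_len - 1L), , drop = FALSE] + dSj
  }
  list(dW = dW, db = db,
       dX = dXp[, (p_l + 1):(p_l + T_len), , drop = FALSE])
}

maxpool2_forward <- function(X) {
  d <- dim(X); B <- d[1]; T_len <- d[2]; C <- d[3]
  T2 <- T_len %/% 2L
  odd <- X[, seq(1L, by = 2L, length.out = T2), , drop = FALSE]
  evn <- X[, seq(2L, by = 2L, length.out = T2), , drop = FALSE]
  mask <- odd >= evn             # ties to the earlier sample
  list(out = pmax(odd, evn), mask = mask, T_in = T_len)
}

maxpool2_backward <- function(cache, dOut) {
  d <- dim(dOut); B <- d[1]; T2 <- d[2]; C <- d[3]
  dX <- array(0, c(B, cache$T_in, C))
  dX[, seq(1L, by = 2L, length.out = T2), ] <- dOut * cache$mask
  dX[, seq(2L, by = 2L, length.out = T2), ] <- dOut * !cache$mask
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(Z, Wx, Wh, b, reverse = FALSE) {
  d <- dim(Z); B <- d[1]; T_len <- d[2]; Cin <- d[3]
  u <- ncol(Wh) / 4L
  order_t <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  h <- matrix(0, B, u); c_st <- matrix(0, B, u)
  cache <- vector("list", T_len)
  bmat <- matrix(b, B, 4 * u, byrow = TRUE)
  for (step in seq_along(order_t)) {
    t <- order_t[step]
    Zt <- matrix(Z[, t, ], B, Cin)
    G <- Zt %*% Wx + h %*% Wh + bmat
    i_g <- sigmoid(G[, 1:u, drop = FALSE])
    f_g <- sigmoid(G[, (u + 1):(2 * u), drop = FALSE])
    o_g <- sigmoid(G[, (2 * u + 1):(3 * u), drop = FALSE])
    g_g <- tanh(G[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- c_st
    c_st <- f_g * c_prev + i_g * g_g
    tc <- tanh(c_st)
    h_prev <- h
    h <- o_g * tc
    cache[[step]] <- list(t = t, Zt = Zt, i = i_g, f = f_g, o = o_g, g = g_g,
                          c = c_st, c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(h_final = h, cache = cache, B = B, T_len = T_len, Cin = Cin, u = u)
}

lstm_backward <- function(fwd, Wx, Wh, dh_final) {
  u <- fwd$u; B <- fwd$B; T_len <- fwd$T_len; Cin <- fwd$Cin
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * u)
  dZ <- array(0, c(B, T_len, Cin))
  dh <- dh_final
  dc <- matrix(0, B, u)
  for (step in rev(seq_len(T_len))) {
    cc <- fwd$cache[[step]]
    do_g <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dG <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_g * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$Zt, dG)
    dWh <- dWh + crossprod(cc$h_prev, dG)
    db <- db + colSums(dG)
    dZ[, cc$t, ] <- dZ[, cc$t, ] + dG %*% t(Wx)
    dh <- dG %*% t(Wh)
    dc <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dZ = dZ)
}

# full forward pass; returns probabilities and (optionally) all caches
hnn_forward <- function(params, X, cfg, keep_cache = FALSE) {
  c1 <- conv1d_same_forward(X, params$W1, params$b1, cfg$conv1_kernel)
  p1 <- maxpool2_forward(c1$out)
  c2 <- conv1d_same_forward(p1$out, params$W2, params$b2, cfg$conv2_kernel)
  p2 <- maxpool2_forward(c2$out)
  lf <- lstm_forward(p2$out, params$Wx_f, params$Wh_f, params$bl_f)
  lb <- lstm_forward(p2$out, params$Wx_b, params$Wh_b, params$bl_b,
                     reverse = TRUE)
  U <- cbind(lf$h_final, lb$h_final)
  D1 <- U %*% params$W3
  D1 <- D1 + matrix(params$b3, nrow(D1), length(params$b3), byrow = TRUE)
  A1 <- pmax(D1, 0)
  logit <- drop(A1 %*% params$W4) + params$b4
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (keep_cache) {
    out$cache <- list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, lf = lf, lb = lb,
                      U = U, mask1 = D1 > 0, A1 = A1)
  }
  out
}

# mean binary cross-entropy and full gradient for one batch
hnn_loss_grad <- function(params, X, y, cfg) {
  B <- dim(X)[1]
  fw <- hnn_forward(params, X, cfg, keep_cache = TRUE)
  eps <- 1e-12
  loss <- -mean(y * log(fw$prob + eps) + (1 - y) * log(1 - fw$prob + eps))
  ca <- fw$cache
  dlogit <- matrix((fw$prob - y) / B, B, 1)
  grads <- list()
  grads$W4 <- crossprod(ca$A1, dlogit)
  grads$b4 <- sum(dlogit)
  dA1 <- dlogit %*% t(params$W4)
  dD1 <- dA1 * ca$mask1
  grads$W3 <- crossprod(ca$U, dD1)
  grads$b3 <- colSums(dD1)
  dU <- dD1 %*% t(params$W3)
  u <- cfg$lstm_units
  bf <- lstm_backward(ca$lf, params$Wx_f, params$Wh_f,
                      dU[, 1:u, drop = FALSE])
  bb <- lstm_backward(ca$lb, params$Wx_b, params$Wh_b,
                      dU[, (u + 1):(2 * u), drop = FALSE])
  grads$Wx_f <- bf$dWx; grads$Wh_f <- bf$dWh; grads$bl_f <- bf$db
  grads$Wx_b <- bb$dWx; grads$Wh_b <- bb$dWh; grads$bl_b <- bb$db
  dP2 <- bf$dZ + bb$dZ
  dC2 <- maxpool2_backward(ca$p2, dP2)
  b2g <- conv1d_same_backward(ca$c2, params$W2, dC2)
  grads$W2 <- b2g$dW; grads$b2 <- b2g$db
  dP1 <- b2g$dX
  dC1 <- maxpool2_backward(ca$p1, dP1)
  b1g <- conv1d_same_backward(ca$c1, params$W1, dC1)
  grads$W1 <- b1g$dW; grads$b1 <- b1g$db
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

hnn_eval_loss <- function(params, X, y, cfg, chunk = 256L) {
  n <- dim(X)[1]
  eps <- 1e-12
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    p <- hnn_forward(params, X[idx, , , drop = FALSE], cfg)$prob
    tot <- tot + sum(-(y[idx] * log(p + eps) + (1 - y[idx]) * log(1 - p + eps)))
  }
  tot / n
}

#' Train the hybrid CNN + BiLSTM on a binary task
#'
#' Splits off a stratified validation fraction, balances the remaining
#' training rows by seeded oversampling of the minority class, and runs Adam
#' on mini-batches of binary cross-entropy with early stopping (patience
#' epochs without validation improvement; the best-validation weights are
#' kept). All randomness (initialization, the validation split, oversampling,
#' batch shuffling) flows from `cfg$seed`.
#'
#' @param X numeric array `[n_samples x n_windows x n_features]`.
#' @param y binary labels (0/1), length `n_samples`.
#' @param cfg an [hnn_config()].
#' @return A trained `hnn_model`; `training_meta` records epochs run, the best
#'   epoch, per-epoch training/validation losses and the seed.
#' @export
train_hnn <- function(X, y, cfg = hnn_config()) {
  stopifnot(length(dim(X)) == 3, dim(X)[1] == length(y))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  model <- build_hnn(dim(X)[2:3], cfg)
  params <- model$params

  hist_train <- numeric(0); hist_val <- numeric(0)
  meta <- with_local_seed(cfg$seed + 1L, {
    # stratified validation split
    val_idx <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      n_val <- max(1L, round(cfg$val_fraction * length(idx)))
      sample(idx, min(n_val, length(idx) - 1L))
    }))
    tr_idx <- setdiff(seq_along(y), val_idx)
    # oversample the minority class within the training portion only
    bal <- oversample_indices(y[tr_idx])
    tr_idx <- tr_idx[bal]
    Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , , drop = FALSE]; yval <- y[val_idx]

    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    n_tr <- length(ytr)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      n_batches <- 0L
      for (s in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- ord[s:min(n_tr, s + cfg$batch_size - 1L)]
        lg <- hnn_loss_grad(params, Xtr[idx, , , drop = FALSE], ytr[idx], cfg)
        upd <- adam_step(params, lg$grads, state, cfg$learning_rate)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lg$loss
        n_batches <- n_batches + 1L
      }
      hist_train[epoch] <- ep_loss / n_batches
      vl <- hnn_eval_loss(params, Xval, yval, cfg)
      hist_val[epoch] <- vl
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    list(best = best, epochs_run = epoch,
         train_loss = hist_train, val_loss = hist_val)
  })

  model$params <- meta$best$params
  model$trained <- TRUE
  model$training_meta <- list(
    seed = cfg$seed, epochs_run = meta$epochs_run,
    best_epoch = meta$best$epoch, best_val_loss = meta$best$loss,
    train_loss = meta$train_loss, val_loss = meta$val_loss
  )
  model
}

#' @export
print.hnn_model <- function(x, ...) {
  cat(sprintf(
    "<hnn_model> conv(%d@%d)-pool-conv(%d@%d)-pool-BiLSTM(%d)-dense(%d)-sigmoid\n",
    x$cfg$conv1_filters, x$cfg$conv1_kernel, x$cfg$conv2_filters,
    x$cfg$conv2_kernel, x$cfg$lstm_units, x$cfg$dense_units
  ))
  cat(sprintf("  input [%d x %d], %d parameters, %s\n",
              x$input_shape[1], x$input_shape[2], hnn_param_count(x),
              if (x$trained) sprintf("trained (best epoch %d)",
                                     x$training_meta$best_epoch)
              else "untrained"))
  invisible(x)
}

#' Predict with a trained hybrid network
#'
#' @param object a trained `hnn_model`.
#' @param newdata array `[n x n_windows x n_features]` matching the model's
#'   input shape.
#' @param type `"score"` (sigmoid probabilities) or `"label"` (threshold 0.5,
#'   ties to the positive class).
#' @param ... ignored.
#' @return Numeric scores in `[0, 1]` or integer 0/1 labels.
#' @export
predict.hnn_model <- function(object, newdata, type = c("score", "label"),
                              ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) != 3 ||
      !all(dim(newdata)[2:3] == object$input_shape)) {
    stop(sprintf("input shape mismatch: model expects [* x %d x %d]",
                 object$input_shape[1], object$input_shape[2]))
  }
  n <- dim(newdata)[1]
  scores <- numeric(n)
  for (s in seq(1L, n, by = 256L)) {
    idx <- s:min(n, s + 255L)
    scores[idx] <- hnn_forward(object$params,
                               newdata[idx, , , drop = FALSE],
                               object$cfg)$prob
  }
  if (type == "score") scores else as.integer(scores >= 0.5)
}
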