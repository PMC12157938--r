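# indices balancing a binary label vector by duplicating minority rows;
# all original rows are always retained
oversample_indices <- function(y) {
  cls <- unique(y)
  if (length(cls) < 2) stop("oversampling needs both classes present")
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  deficit <- max(counts) - min(counts)
  idx <- seq_along(y)
  if (deficit > 0) {
    pool <- which(y == minority)
    idx <- c(idx, sample(pool, deficit, replace = TRUE))
  }
  idx
}

#' Balance a binary training set by random oversampling
#'
#' Duplicates rows of the minority class by seeded sampling with replacement
#' until both class counts are equal; every original row is retained.
#'
#' @param x feature rows: a matrix or an array whose first dimension indexes
#'   samples.
#' @param y binary labels, one per row.
#' @param seed integer seed for the resampling draws.
#' @return List with balanced `x` and `y`.
#' @export
#' @examples
#' b <- oversample_balance(matrix(1:28, 14), rep(c(0, 1), c(4, 10)), seed = 1)
#' table(b$y)
oversample_balance <- function(x, y, seed = 1) {
  idx <- with_local_seed(seed, oversample_indices(y))
  x_bal <- if (is.matrix(x)) {
    x[idx, , drop = FALSE]
  } else if (is.array(x) && length(dim(x)) == 3) {
    x[idx, , , drop = FALSE]
  } else if (is.array(x) && length(dim(x)) == 4) {
    x[idx, , , , drop = FALSE]
  } else {
    x[idx]
  }
  list(x = x_bal, y = y[idx])
}

# ---- shrinkage LDA for p >> n feature matrices -----------------------------
# Ledoit-Wolf shrinkage toward the scaled identity; the discriminant solve
# uses the Woodbury identity so only an n x n system is ever factorized.
fit_lda_shrink <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  pri <- mean(y == 1)
  Xc <- X
  Xc[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  Xc[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  n <- nrow(Xc); p <- ncol(Xc)
  # Ledoit-Wolf intensity (target m*I), computed without forming S (p x p)
  G <- Xc %*% t(Xc)                    # n x n Gram
  trS <- sum(diag(G)) / n              # = tr(S), S = Xc'Xc / n
  m <- trS / p
  normS2 <- sum(G^2) / n^2             # = ||S||_F^2
  d2 <- normS2 - 2 * m * trS + p * m^2 # ||S - mI||_F^2
  b2bar <- (sum(rowSums(Xc^2)^2) - n * normS2) / n^2
  b2 <- min(d2, b2bar)
  rho <- if (d2 > 0) b2 / d2 else 1
  rho <- min(max(rho, 1e-6), 1)
  # Sigma = (1-rho) Xc'Xc/n + rho m I ; w = Sigma^{-1} (mu1 - mu0) via Woodbury
  a <- rho * m
  dvec <- mu1 - mu0
  if (rho >= 1 - 1e-12) {
    w <- dvec / a
  } else {
    c1 <- (1 - rho) / n
    A <- diag(n) + (c1 / a) * G
    t1 <- Xc %*% dvec
    w <- (dvec - (c1 / a) * drop(t(Xc) %*% solve(A, t1))) / a
  }
  bias <- -sum(w * (mu0 + mu1)) / 2 + log(pri / (1 - pri))
  structure(list(w = w, bias = bias, rho = rho, m = m), class = "lda_shrink")
}

#' @export
predict.lda_shrink <- function(object, newdata, ...) {
  drop(newdata %*% object$w) + object$bias   # signed discriminant score
}

fit_svm_rbf <- function(X, y) {
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = 1, scale = TRUE)
  # orientation of decision values depends on which level e1071 saw first;
  # record it so scores always increase with class 1
  dv <- drop(attr(predict(fit, X, decision.values = TRUE), "decision.values"))
  r <- stats::cor(dv, as.numeric(y))
  orient <- if (!is.na(r) && r < 0) -1 else 1
  structure(list(fit = fit, orient = orient), class = "svm_rbf")
}

#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  dv <- drop(attr(predict(object$fit, newdata, decision.values = TRUE),
                  "decision.values"))
  object$orient * dv
}

# fit one binary classifier of the requested family on already-relabeled data
fit_binary <- function(kind, X, y, cfg, seed) {
  switch(kind,
    hnn = {
      cfg <- cfg %||% hnn_config()
      cfg$seed <- as.integer(seed)
      train_hnn(X, y, cfg)
    },
    lda = fit_lda_shrink(X, y),
    svm = fit_svm_rbf(X, y),
    stop("unknown classifier kind: ", kind)
  )
}

score_binary <- function(fit, X) {
  if (inherits(fit, "hnn_model")) {
    predict(fit, X, type = "score")
  } else {
    stats::plogis(predict(fit, X))     # monotone map of the decision value
  }
}

#' Train a one-vs-rest classifier for one target gesture
#'
#' Relabels the tensor's gesture labels as target-vs-rest, performs a
#' stratified trial-level 80/20 split, balances the training portion by
#' oversampling (baselines; the hybrid network additionally balances
#' internally after carving its validation split), fits the requested
#' classifier, and scores the held-out 20%. The hybrid network consumes the
#' tensor as a `[windows x (channels*features)]` sequence; LDA/SVM consume it
#' flattened per trial.
#'
#' @param feats a [extract_features()] tensor.
#' @param target gesture label to detect (positive class).
#' @param kind `"hnn"`, `"lda"` or `"svm"`.
#' @param labels optional label override (defaults to the tensor's).
#' @param cfg optional [hnn_config()] for the hybrid network.
#' @param split training fraction of the 80/20 protocol (default 0.8).
#' @param seed integer seed (split, oversampling, network training).
#' @return An object of class `ovr_model` with the fitted state, `input_spec`,
#'   held-out predictions (`heldout$scores`, `heldout$labels`) and
#'   `training_meta`.
#' @export
train_ovr <- function(feats, target, kind = c("hnn", "lda", "svm"),
                      labels = NULL, cfg = NULL, split = 0.8, seed = 1) {
  stopifnot(inherits(feats, "feature_tensor"))
  kind <- match.arg(kind)
  labels <- labels %||% feats$gesture_labels
  if (!target %in% labels) stop("target gesture absent from labels")
  ybin <- as.integer(labels == target)
  n <- length(ybin)

  idx_split <- with_local_seed(seed, {
    tr <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(ybin == cl)
      sample(idx, round(split * length(idx)))
    }))
    sort(tr)
  })
  te <- setdiff(seq_len(n), idx_split)
  if (length(unique(ybin[idx_split])) < 2 || length(te) < 1) {
    stop("degenerate split: need both classes in training and a test set")
  }

  Xall <- if (kind == "hnn") sequence_tensor(feats) else flatten_tensor(feats)
  sub <- function(idx) {
    if (kind == "hnn") Xall[idx, , , drop = FALSE] else
      Xall[idx, , drop = FALSE]
  }

  if (kind == "hnn") {
    # the network oversamples internally, after its validation split
    fit <- fit_binary("hnn", sub(idx_split), ybin[idx_split], cfg, seed)
  } else {
    bal <- oversample_balance(sub(idx_split), ybin[idx_split], seed = seed)
    fit <- fit_binary(kind, bal$x, bal$y, cfg, seed)
  }
  scores <- score_binary(fit, sub(te))

  structure(
    list(kind = kind, fit = fit, target = as.integer(target),
         input_spec = list(dim = dim(feats$values)[-1],
                           variant = feats$variant),
         threshold = 0.5,
         heldout = list(index = te, scores = scores,
                        labels = ybin[te]),
         training_meta = list(seed = seed, split = split,
                              n_train = length(idx_split),
                              n_test = length(te))),
    class = "ovr_model"
  )
}

#' @export
print.ovr_model <- function(x, ...) {
  acc <- mean((x$heldout$scores >= x$threshold) == (x$heldout$labels == 1))
  cat(sprintf(
    "<ovr_model> %s vs-rest for gesture %d; held-out accuracy %.3f (n=%d)\n",
    toupper(x$kind), x$target, acc, length(x$heldout$labels)
  ))
  invisible(x)
}

#' Predict with a one-vs-rest model
#'
#' @param object an [train_ovr()] model.
#' @param newdata a `feature_tensor` of the same variant/shape, or the
#'   corresponding numeric array.
#' @param type `"score"` for values in `[0, 1]`, `"label"` for 0/1 at the 0.5
#'   threshold (ties positive).
#' @param ... ignored.
#' @return Numeric scores or integer labels.
#' @export
predict.ovr_model <- function(object, newdata, type = c("score", "label"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_tensor")) {
    if (!all(dim(newdata$values)[-1] == object$input_spec$dim)) {
      stop("feature tensor shape does not match the model's input_spec")
    }
    newdata <- if (object$kind == "hnn") sequence_tensor(newdata) else
      flatten_tensor(newdata)
  } else {
    expect <- if (object$kind == "hnn") {
      c(object$input_spec$dim[1],
        object$input_spec$dim[2] * object$input_spec$dim[3])
    } else {
      prod(object$input_spec$dim)
    }
    got <- dim(newdata)[-1]
    if (length(got) != length(expect) || !all(got == expect)) {
      stop("input shape mismatch with the model's input_spec")
    }
  }
  scores <- score_binary(object$fit, newdata)
  if (type == "score") scores else as.integer(scores >= object$threshold)
}
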