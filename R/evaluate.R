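#' Deterministic k-fold split
#'
#' Disjoint, exhaustive folds whose sizes differ by at most one (the first
#' `n %% k` folds take the extra trial). In subject-grouped mode every
#' subject's trials land in a single fold (subjects are assigned greedily to
#' the currently smallest fold).
#'
#' @param n number of trials.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed for the shuffle.
#' @param grouping `"trial"` (default) or `"subject"`.
#' @param subjects subject id per trial, required for subject grouping.
#' @return List of `k` integer index vectors.
#' @export
#' @examples
#' lengths(kfold_split(1386, 5, seed = 1))
kfold_split <- function(n, k = 5, seed = 1, grouping = c("trial", "subject"),
                        subjects = NULL) {
  grouping <- match.arg(grouping)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop(sprintf("cannot make %d folds from %d trials", k, n))
  with_local_seed(seed, {
    if (grouping == "trial") {
      ord <- sample.int(n)
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      unname(split(ord, rep(seq_len(k), sizes)))
    } else {
      if (is.null(subjects) || length(subjects) != n) {
        stop("subject grouping needs one subject id per trial")
      }
      subj <- sample(unique(subjects))
      folds <- vector("list", k)
      load <- integer(k)
      for (s in subj) {
        j <- which.min(load)
        folds[[j]] <- c(folds[[j]], which(subjects == s))
        load[j] <- load[j] + sum(subjects == s)
      }
      if (any(lengths(folds) == 0)) {
        stop("fewer subjects than folds: cannot group by subject")
      }
      folds
    }
  })
}

#' Binary confusion counts
#'
#' @param y_true,y_pred binary (0/1 or logical) vectors of equal length; 1 is
#'   the target gesture.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1)) {
    stop("labels must be binary (0/1)")
  }
  structure(
    list(TP = sum(y_true == 1 & y_pred == 1),
         TN = sum(y_true == 0 & y_pred == 0),
         FP = sum(y_true == 0 & y_pred == 1),
         FN = sum(y_true == 1 & y_pred == 0)),
    class = "confusion_counts"
  )
}

#' Accuracy and F1 from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + TN + FP + FN)`; F1 is
#' `TP / (TP + (FP + FN) / 2)`, defined as 0 (with a message) when no
#' positives exist anywhere (`TP + FP + FN = 0`).
#'
#' @param c a [confusion()] object.
#' @return Scalar metric in `[0, 1]`.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) stop("empty confusion counts")
  (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
f1_score <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- c$TP + (c$FP + c$FN) / 2
  if (denom == 0) {
    message("F1 undefined (no positives anywhere); returning 0 by convention")
    return(0)
  }
  c$TP / denom
}

# area under the ROC curve by the rank (Mann-Whitney) formula
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Zero differences are dropped and ties mid-ranked. For `n <= 25` retained
#' pairs the null distribution of `W+` is computed exactly by the
#' generating-function recursion over the (doubled, hence integral) ranks --
#' exact even under ties, where the classical table approach gives up. Above
#' 25 pairs a normal approximation with continuity and tie correction is used.
#'
#' @param a,b paired score vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @return List with `statistic` (W+, the positive-rank sum), `p.value`, `n`
#'   (pairs retained) and `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all pairs are tied")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25) {
    # exact tail via the distribution of sum of a random subset of the ranks
    r2 <- as.integer(round(2 * r))          # doubled mid-ranks are integers
    tot <- sum(r2)
    dist <- numeric(tot + 1)                # index i -> P(2*W+ = i - 1) * 2^n
    dist[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), dist[seq_len(tot + 1 - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):(tot + 1)])
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_le, p_ge))
    )
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_ge <- (w_pos - mu - cc) / sqrt(sig2)
    z_le <- (w_pos - mu + cc) / sqrt(sig2)
    p <- switch(alternative,
      greater = stats::pnorm(z_ge, lower.tail = FALSE),
      less = stats::pnorm(z_le),
      two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                 stats::pnorm(z_ge, lower.tail = FALSE)))
    )
    method <- "normal approximation"
  }
  list(statistic = w_pos, p.value = p, n = n, method = method)
}

# per-gesture k-fold OvR cross-validation of one classifier on one tensor
cv_ovr <- function(feats, kind, gestures, folds, cfg = NULL, seed = 1) {
  labels <- feats$gesture_labels
  Xseq <- if (kind == "hnn") sequence_tensor(feats) else flatten_tensor(feats)
  sub <- function(idx) {
    if (kind == "hnn") Xseq[idx, , , drop = FALSE] else
      Xseq[idx, , drop = FALSE]
  }
  rows <- list()
  for (g in gestures) {
    ybin <- as.integer(labels == g)
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      tr <- setdiff(seq_along(labels), te)
      bal <- with_local_seed(seed + 97L * f + g, oversample_indices(ybin[tr]))
      tr_bal <- tr[bal]
      fit <- if (kind == "hnn") {
        fit_binary("hnn", sub(tr), ybin[tr], cfg, seed + 97L * f + g)
      } else {
        fit_binary(kind, sub(tr_bal), ybin[tr_bal], cfg, seed)
      }
      scores <- score_binary(fit, sub(te))
      cm <- confusion(ybin[te], as.integer(scores >= 0.5))
      rows[[length(rows) + 1]] <- data.frame(
        classifier = kind, gesture = g, fold = f,
        accuracy = accuracy(cm), f1 = f1_score(cm),
        auroc = auroc(scores, ybin[te])
      )
    }
  }
  do.call(rbind, rows)
}

#' Run a Table-style experiment matrix
#'
#' For each cell of the requested (feature variant x channel set x
#' classifier) grid: extract features, run one-vs-rest k-fold cross-validation
#' per gesture, and collect per-fold accuracy/F1/AUROC. Folds are shared
#' across classifiers and gestures (same seed), so classifier comparisons are
#' paired per (gesture, fold); those pairs feed two-sided Wilcoxon signed-rank
#' tests per metric. Aggregates are unweighted means over gestures and folds.
#'
#' @param ts a [trialset()].
#' @param variants feature variants to run (see [extract_features()]).
#' @param channel_sets list of channel-label vectors, or `NULL` entries for
#'   all channels.
#' @param classifiers subset of `c("lda", "svm", "hnn")`.
#' @param gestures gesture labels to evaluate (default: all present).
#' @param k folds (default 5).
#' @param seed integer seed for folds and training.
#' @param hnn_cfg optional [hnn_config()].
#' @param grouping fold grouping, see [kfold_split()].
#' @param ... further arguments to [extract_features()].
#' @return An object of class `cv_report`: `per_fold` (one row per cell x
#'   gesture x fold), `aggregate` (one row per cell), `comparisons` (pairwise
#'   Wilcoxon per cell-config and metric).
#' @export
run_experiment <- function(ts, variants = "hos_if_ia",
                           channel_sets = list(NULL),
                           classifiers = c("lda", "svm"),
                           gestures = NULL, k = 5, seed = 1,
                           hnn_cfg = NULL, grouping = "trial", ...) {
  stopifnot(inherits(ts, "trialset"))
  gestures <- gestures %||% sort(unique(ts$gesture_labels))
  n <- dim(ts$trials)[1]
  folds <- kfold_split(n, k, seed = seed, grouping = grouping,
                       subjects = ts$subject_ids)
  per_fold <- list()
  for (variant in variants) {
    for (chs in channel_sets) {
      feats <- extract_features(ts, variant = variant, channels = chs, ...)
      ch_lab <- if (is.null(chs)) "all" else paste(chs, collapse = ",")
      for (kind in classifiers) {
        res <- cv_ovr(feats, kind, gestures, folds, cfg = hnn_cfg, seed = seed)
        res$variant <- variant
        res$channels <- ch_lab
        per_fold[[length(per_fold) + 1]] <- res
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)

  agg <- stats::aggregate(
    per_fold[, c("accuracy", "f1", "auroc")],
    by = per_fold[, c("variant", "channels", "classifier")],
    FUN = mean
  )

  comparisons <- list()
  cells <- unique(per_fold[, c("variant", "channels")])
  for (ci in seq_len(nrow(cells))) {
    sel <- per_fold$variant == cells$variant[ci] &
      per_fold$channels == cells$channels[ci]
    kinds <- unique(per_fold$classifier[sel])
    if (length(kinds) < 2) next
    prs <- utils::combn(kinds, 2, simplify = FALSE)
    for (pr in prs) {
      for (metric in c("accuracy", "f1")) {
        a <- per_fold[sel & per_fold$classifier == pr[1], ]
        b <- per_fold[sel & per_fold$classifier == pr[2], ]
        key <- paste(a$gesture, a$fold)
        b <- b[match(key, paste(b$gesture, b$fold)), ]
        wt <- tryCatch(
          wilcoxon_signed_rank(a[[metric]], b[[metric]]),
          error = function(e) list(statistic = NA_real_, p.value = NA_real_,
                                   n = 0)
        )
        comparisons[[length(comparisons) + 1]] <- data.frame(
          variant = cells$variant[ci], channels = cells$channels[ci],
          metric = metric, model_a = pr[1], model_b = pr[2],
          statistic = wt$statistic, p.value = wt$p.value, n_pairs = wt$n
        )
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else NULL

  structure(
    list(per_fold = per_fold, aggregate = agg, comparisons = comparisons,
         k = k, seed = seed, gestures = gestures),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold OvR cross-validation, gestures %s\n",
              x$k, paste(x$gestures, collapse = " ")))
  print(x$aggregate, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("pairwise Wilcoxon signed-rank comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
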