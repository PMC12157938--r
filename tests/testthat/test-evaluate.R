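test_that("k-fold splits have the documented sizes and partition the data", {
  f <- kfold_split(1386, 5, seed = 1)
  expect_equal(sort(lengths(f), decreasing = TRUE),
               c(278, 277, 277, 277, 277))
  expect_equal(lengths(f)[1], 278L)  # first fold takes the remainder

  expect_true(all(lengths(kfold_split(10, 5, seed = 1)) == 2))
  expect_error(kfold_split(3, 5), "cannot make")
  expect_error(kfold_split(10, 1), "at least 2")
})

test_that("folds partition the index set for random (n, k)", {
  set.seed(50)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    k <- sample(2:min(10, n), 1)
    f <- kfold_split(n, k, seed = i)
    expect_equal(sort(unlist(f)), 1:n)
    expect_lte(diff(range(lengths(f))), 1)
  }
})

test_that("subject grouping keeps each subject's trials in one fold", {
  subjects <- rep(1:9, each = 4)
  f <- kfold_split(36, 3, seed = 2, grouping = "subject", subjects = subjects)
  expect_equal(sort(unlist(f)), 1:36)
  for (fold in f) {
    subj_in <- unique(subjects[fold])
    for (s in subj_in) expect_true(all(which(subjects == s) %in% fold))
  }
})

test_that("confusion counts follow the one-vs-rest definitions", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cm$TP, 1); expect_equal(cm$FN, 1)
  expect_equal(cm$TN, 1); expect_equal(cm$FP, 1)

  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0)

  expect_error(confusion(c(1, 0), c(1)), "length mismatch")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")

  # counts sum to n on random instances (brute-force recount)
  set.seed(60)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    yt <- rbinom(n, 1, 0.4); yp <- rbinom(n, 1, 0.5)
    cm <- confusion(yt, yp)
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, n)
    expect_equal(cm$TP, sum(yt & yp))
  }
})

test_that("accuracy and F1 match brute-force recounts on random label pairs", {
  cm <- structure(list(TP = 3, TN = 5, FP = 1, FN = 1),
                  class = "confusion_counts")
  expect_equal(accuracy(cm), 0.8)
  expect_equal(f1_score(structure(list(TP = 3, TN = 0, FP = 1, FN = 1),
                                  class = "confusion_counts")), 0.75)
  expect_equal(accuracy(confusion(c(1, 0), c(1, 0))), 1)
  expect_equal(accuracy(confusion(rep(c(1, 0), 5), rep(c(0, 1), 5))), 0)
  expect_message(
    expect_equal(f1_score(confusion(rep(0, 4), rep(0, 4))), 0),
    "convention"
  )

  set.seed(61)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    yt <- rbinom(n, 1, 0.5); yp <- rbinom(n, 1, 0.5)
    cm <- confusion(yt, yp)
    expect_equal(accuracy(cm), mean(yt == yp))
    tp <- sum(yt & yp); fp <- sum(!yt & yp); fn <- sum(yt & !yp)
    f1_brute <- if (tp + (fp + fn) / 2 == 0) 0 else tp / (tp + (fp + fn) / 2)
    expect_equal(suppressMessages(f1_score(cm)), f1_brute)
  }
})

test_that("exact Wilcoxon p-values match full sign enumeration up to n = 12", {
  # the textbook case: five one-signed differences, one-sided p = 1/32
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), rep(1, 5),
                              alternative = "greater")
  expect_equal(res$p.value, 1 / 32)

  set.seed(70)
  for (n in c(5, 8, 10, 12)) {
    for (rep in 1:3) {
      a <- round(rnorm(n), 1)
      b <- round(rnorm(n), 1)
      if (all(a == b)) next
      ours <- wilcoxon_signed_rank(a, b)
      expect_equal(ours$p.value, enum_wilcoxon_p(a, b), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }

  # agreement with stats::wilcox.test in the tie-free exact regime
  a <- c(1.3, -0.2, 2.1, 0.7, -1.5, 0.4, 2.2, -0.9)
  b <- c(0.1, 0.3, -0.8, 0.2, 0.5, -0.6, 1.0, 0.8)
  expect_equal(wilcoxon_signed_rank(a, b)$p.value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
})

test_that("the signed-rank statistic is symmetric under argument swap", {
  set.seed(71)
  a <- rnorm(10); b <- rnorm(10)
  f <- wilcoxon_signed_rank(a, b)
  r <- wilcoxon_signed_rank(b, a)
  n <- f$n
  expect_equal(f$statistic + r$statistic, n * (n + 1) / 2)  # W+ <-> W-
  expect_equal(f$p.value, r$p.value)
})

test_that("normal-approximation branch engages above 25 pairs", {
  set.seed(72)
  a <- rnorm(40); b <- rnorm(40) + 0.8
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(res$p.value, ref, tolerance = 1e-9)
})

test_that("run_experiment produces one row per cell and paired comparisons", {
  ts <- small_trialset()[1:56]  # 2 subjects x 7 gestures x 4 reps
  rep_out <- run_experiment(
    ts, variants = "bandpower",
    channel_sets = list(NULL, c("C3", "Cz", "C4")),
    classifiers = c("lda", "svm"),
    gestures = c(0, 1), k = 3, seed = 5
  )
  # per-fold rows: 2 channel sets x 2 classifiers x 2 gestures x 3 folds
  expect_equal(nrow(rep_out$per_fold), 2 * 2 * 2 * 3)
  expect_equal(nrow(rep_out$aggregate), 4)
  expect_true(all(rep_out$per_fold$accuracy >= 0 &
                    rep_out$per_fold$accuracy <= 1))
  expect_true(all(rep_out$per_fold$f1 >= 0 & rep_out$per_fold$f1 <= 1))

  # aggregate equals the mean of the per-fold metrics
  for (i in seq_len(nrow(rep_out$aggregate))) {
    sel <- rep_out$per_fold$variant == rep_out$aggregate$variant[i] &
      rep_out$per_fold$channels == rep_out$aggregate$channels[i] &
      rep_out$per_fold$classifier == rep_out$aggregate$classifier[i]
    expect_equal(rep_out$aggregate$accuracy[i],
                 mean(rep_out$per_fold$accuracy[sel]), tolerance = 1e-12)
  }

  # comparisons: 2 cells x 1 classifier pair x 2 metrics
  expect_equal(nrow(rep_out$comparisons), 4)
  expect_true(all(rep_out$comparisons$n_pairs <= 6))

  single <- run_experiment(ts, variants = "bandpower",
                           channel_sets = list(c("C3", "Cz", "C4")),
                           classifiers = "lda", gestures = 0, k = 3, seed = 5)
  expect_equal(nrow(single$aggregate), 1)
  expect_null(single$comparisons)
})

test_that("auroc agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(80)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.4)
  ours <- ewtbci:::auroc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
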