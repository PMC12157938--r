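test_that("Welch PSD integrates to the variance and localizes tones", {
  set.seed(2)
  w <- rnorm(1e4)
  p <- welch_psd(w, 100)
  df <- 100 / 256
  expect_equal(sum(p$psd) * df, stats::var(w), tolerance = 0.01)

  tone <- make_tone(12, 1, 250, 2000)$samples
  pt <- welch_psd(tone, 250)
  expect_equal(pt$freq[which.max(pt$psd)], 12, tolerance = 250 / 256)

  expect_true(all(welch_psd(rep(0, 500), 250)$psd == 0))
  expect_error(welch_psd(rnorm(100), 250, seg_len = 200), "longer")
})

test_that("sensitive-mode selection maximizes above-2-Hz power", {
  fs <- 250; n <- 1250
  fake_modes <- function(rows) {
    structure(list(modes = do.call(rbind, rows)), class = "ewt_modes")
  }
  m <- fake_modes(list(
    3 * make_tone(12, 1, fs, n)$samples,   # strong 12 Hz
    0.5 * make_tone(20, 1, fs, n)$samples, # weak 20 Hz
    1e-3 * rnorm(n)                        # near-zero noise
  ))
  expect_equal(select_sensitive_mode(m, fs), 1L)

  single <- fake_modes(list(rnorm(n)))
  expect_equal(select_sensitive_mode(single, fs), 1L)

  # all power at 1 Hz is excluded; moderate 10 Hz wins
  m2 <- fake_modes(list(
    10 * make_tone(1, 1, fs, n)$samples,
    make_tone(10, 1, fs, n)$samples
  ))
  expect_equal(select_sensitive_mode(m2, fs), 2L)
})

test_that("the analytic signal reproduces the Hilbert pair of a tone", {
  fs <- 250; n <- 1250
  t <- (0:(n - 1)) / fs
  x <- cos(2 * pi * 15 * t)
  a <- analytic_signal(x)
  interior <- 100:1150
  expect_lt(max(abs(Im(a$z[interior]) - sin(2 * pi * 15 * t[interior]))), 1e-3)
  expect_lt(max(abs(a$ia[interior] - 1)), 0.01)

  z <- analytic_signal(rep(0, 64))
  expect_true(all(z$ia == 0))
  expect_true(all(z$phase == 0))
  expect_error(analytic_signal(rnorm(4)), "too short")
})

test_that("instantaneous frequency recovers tone and chirp truth", {
  interior <- 100:1150
  for (amp in c(0.1, 1, 10)) {
    fx <- make_tone(15, amp, 250, 1250)
    a <- analytic_signal(fx$samples)
    iff <- instantaneous_frequency(a, 250)
    expect_lt(max(abs(iff[interior] - 15)), 0.15)      # IF scale-invariant
    expect_lt(max(abs(a$ia[interior] - amp)), 0.01 * max(amp, 1))  # IA linear
  }
  ch <- make_chirp(8, 25, 1, 250, 1250)
  ac <- analytic_signal(ch$samples)
  ifc <- instantaneous_frequency(ac, 250)
  expect_lt(max(abs(ifc[interior] - ch$truth_if[interior])), 0.5)

  # constant signal: constant phase, zero IF
  cz <- analytic_signal(rep(3, 100))
  expect_true(all(abs(instantaneous_frequency(cz, 250)) < 1e-9))
})

test_that("higher-order statistics match their worked values", {
  expect_equal(hos_mad(c(1, 2, 3, 4)), 1.0)
  expect_equal(hos_mad(rep(5, 10)), 0)
  expect_equal(hos_mad(c(0, 0, 0, 4)), 1.5)

  expect_equal(hos_iqr(c(1, 2, 3, 4)), 2.0)    # 3.5 - 1.5
  expect_equal(hos_iqr(c(1, 2, 3, 4, 5)), 3.0) # 4.5 - 1.5, median excluded
  expect_equal(hos_iqr(rep(2, 6)), 0)

  expect_equal(hos_skewness(c(-1, 0, 1)), 0)
  expect_equal(hos_skewness(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12)
  expect_error(hos_skewness(rep(1, 5)), "zero variance")

  expect_equal(hos_kurtosis(c(-1, 1, -1, 1)), 1.0)
  expect_error(hos_kurtosis(rep(1, 5)), "zero variance")
})

test_that("kurtosis of many Gaussian draws approaches 3", {
  set.seed(31)
  expect_equal(hos_kurtosis(rnorm(1e6)), 3.0, tolerance = 0.05 / 3)
})

test_that("HOS transform as theory dictates under affine maps", {
  set.seed(12)
  x <- rnorm(200)^2  # skewed sample
  shift <- x + 17.3
  expect_equal(hos_mad(shift), hos_mad(x))
  expect_equal(hos_iqr(shift), hos_iqr(x))
  scaled <- 2.5 * x - 4
  expect_equal(hos_skewness(scaled), hos_skewness(x), tolerance = 1e-12)
  expect_equal(hos_kurtosis(scaled), hos_kurtosis(x), tolerance = 1e-12)
})

test_that("bandpower is the mean square and scales quadratically", {
  expect_equal(bandpower(rep(0, 50)), 0)
  # unit tone over whole periods: mean cos^2 = 1/2
  w <- make_tone(10, 1, 250, 250)$samples  # 10 full periods
  expect_equal(bandpower(w), 0.5, tolerance = 1e-12)
  x <- rnorm(30)
  expect_equal(bandpower(2 * x), 4 * bandpower(x))
  expect_error(bandpower(numeric(0)), "empty")
})

test_that("feature tensors have the documented shapes", {
  ts <- small_trialset()[1:4]
  ft2 <- extract_features(ts, variant = "hos_if_ia")
  expect_equal(dim(ft2$values), c(4, 61, 8, 8))
  expect_length(ft2$feature_names, 8)

  ft1 <- extract_features(ts, variant = "bandpower",
                          channels = c("C3", "Cz", "C4"))
  expect_equal(dim(ft1$values), c(4, 61, 3, 1))

  ftr <- extract_features(ts[1:2], variant = "raw_mode")
  expect_equal(dim(ftr$values), c(2, 61, 8, 50))

  empty <- ts[integer(0)]
  fte <- extract_features(empty, variant = "bandpower")
  expect_equal(dim(fte$values)[1], 0)
  expect_equal(fte$variant, "bandpower")
  expect_equal(dim(fte$values)[2], 61)
})

test_that("feature extraction is deterministic", {
  ts <- small_trialset()[1:2]
  a <- extract_features(ts, variant = "hos_ia", channels = c("C3", "Cz"))
  b <- extract_features(ts, variant = "hos_ia", channels = c("C3", "Cz"))
  expect_identical(a$values, b$values)
})

test_that("IA statistics separate gesture classes and the effect grows with delta", {
  pval_at <- function(delta) {
    ts <- generate_trialset(n_subjects = 3, n_gestures = 2, n_reps = 4,
                            class_separation = delta, seed = 55)
    ft <- extract_features(ts, variant = "hos_ia",
                           channels = c("C3", "Cz", "C4"))
    # per-trial mean of the IA mean-absolute-deviation feature
    feat <- apply(ft$values[, , , 1, drop = FALSE], 1, mean)
    g <- ft$gesture_labels
    stats::wilcox.test(feat[g == 0], feat[g == 1])$p.value
  }
  p_strong <- pval_at(3)
  p_weak <- pval_at(0.3)
  expect_lt(p_strong, 0.01)
  expect_lt(p_strong, p_weak)
})
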