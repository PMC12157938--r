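test_that("spectrum peaks where the tone is and satisfies Parseval", {
  x <- make_tone(15, 1, 250, 1250)$samples
  sp <- compute_spectrum(x)
  expect_equal(sp$omega[which.max(sp$magnitudes)], 2 * pi * 15 / 250,
               tolerance = 1e-9)

  z <- compute_spectrum(rep(0, 64))
  expect_true(all(z$magnitudes == 0))

  # energy: sum over the full grid of |X|^2 / n equals sum(x^2)
  y <- rnorm(501)
  spy <- compute_spectrum(y)
  n <- spy$n_fft
  full <- c(spy$magnitudes^2, rev(spy$magnitudes[2:(length(spy$magnitudes) -
                                                      (1 - n %% 2))]^2))
  expect_equal(sum(full) / n, sum(y^2), tolerance = 1e-9)

  expect_error(compute_spectrum(c(1, 2)), "too short")
})

test_that("boundaries fall at the inter-peak minimum of the smoothed spectrum", {
  # synthetic spectrum: two Gaussian bumps at 0.8 and 2.0 rad
  n_fft <- 1024
  half <- floor(n_fft / 2) + 1
  omega <- 2 * pi * (0:(half - 1)) / n_fft
  mag <- exp(-(omega - 0.8)^2 / (2 * 0.05^2)) +
    0.8 * exp(-(omega - 2.0)^2 / (2 * 0.05^2))
  spec <- structure(list(magnitudes = mag, omega = omega, n_fft = n_fft),
                    class = "ewt_spectrum")
  b <- detect_boundaries(spec, K = 2, smoothing = 2)
  expect_length(b$boundaries, 1)
  expect_gt(b$boundaries, 0.8)
  expect_lt(b$boundaries, 2.0)
  # brute-force oracle: scan every bin between the two true peak locations
  sm <- ewtbci:::smooth_spectrum(mag, 2)
  peaks <- c(which.min(abs(omega - 0.8)), which.min(abs(omega - 2.0)))
  between <- (peaks[1] + 1):(peaks[2] - 1)
  expect_equal(b$boundaries, omega[between[which.min(sm[between])]])

  # K = 1: no boundaries
  expect_length(detect_boundaries(spec, K = 1)$boundaries, 0)

  # flat spectrum: warning and K reduced
  flat <- structure(list(magnitudes = rep(1, half), omega = omega,
                         n_fft = n_fft), class = "ewt_spectrum")
  expect_warning(bf <- detect_boundaries(flat, K = 3), "reducing K")
  expect_lt(bf$K, 3)
})

test_that("boundary detection is invariant to uniform spectrum scaling", {
  x <- rnorm(800)
  s1 <- compute_spectrum(x)
  s2 <- s1
  s2$magnitudes <- 7.3 * s2$magnitudes
  b1 <- suppressWarnings(detect_boundaries(s1, 5))
  b2 <- suppressWarnings(detect_boundaries(s2, 5))
  expect_identical(b1$boundaries, b2$boundaries)
})

test_that("every filter bank is a tight frame (partition of unity)", {
  set.seed(99)
  for (rep in 1:100) {
    K <- sample(2:8, 1)
    bnd <- sort(runif(K - 1, 0.05, pi - 0.05))
    # enforce strict separation so boundaries are a valid set
    if (any(diff(bnd) < 0.05)) next
    b <- structure(list(boundaries = bnd, K = K), class = "boundary_set")
    bank <- build_filter_bank(b, n_fft = 512)
    pu <- rowSums(bank$filters^2)
    expect_lt(max(abs(pu - 1)), 1e-10)
  }
})

test_that("degenerate and inadmissible banks behave as specified", {
  b0 <- structure(list(boundaries = numeric(0), K = 1L),
                  class = "boundary_set")
  bank <- build_filter_bank(b0, n_fft = 128)
  expect_true(all(bank$filters == 1))
  x <- rnorm(128)
  m <- ewt_decompose(x, K = 1)
  expect_equal(drop(m$modes), x, tolerance = 1e-12)

  tight <- structure(list(boundaries = c(1.0, 1.05), K = 3L),
                     class = "boundary_set")
  expect_error(build_filter_bank(tight, n_fft = 256, gamma = 0.9),
               "admissibility")
})

test_that("decomposition reconstructs random signals to 1e-8", {
  set.seed(7)
  x <- rnorm(1250)
  m <- suppressWarnings(ewt_decompose(x, K = 10))
  expect_equal(nrow(m$modes), m$boundaries$K)
  expect_lt(max(abs(ewt_reconstruct(m) - x)), 1e-8)

  # single-mode transform is the identity
  m1 <- ewt_decompose(x, K = 1)
  expect_lt(max(abs(ewt_reconstruct(m1) - x)), 1e-10)

  z <- ewt_decompose(rep(0, 100), K = 1)
  expect_true(all(z$modes == 0))
})

test_that("two separated tones land in distinct modes with >= 95% purity", {
  x10 <- make_tone(10, 1, 250, 1250)$samples
  x40 <- make_tone(40, 1, 250, 1250)$samples
  m <- ewt_decompose(x10 + x40, K = 2, smoothing = 3)
  energy_at <- function(sig, f) {
    X <- Mod(stats::fft(sig))^2
    bin <- round(f * length(sig) / 250) + 1
    X[bin] + X[length(sig) - bin + 2]
  }
  e10 <- c(energy_at(m$modes[1, ], 10), energy_at(m$modes[2, ], 10))
  e40 <- c(energy_at(m$modes[1, ], 40), energy_at(m$modes[2, ], 40))
  expect_gt(e10[1] / sum(e10), 0.95)  # 10 Hz concentrated in the low mode
  expect_gt(e40[2] / sum(e40), 0.95)  # 40 Hz concentrated in the high mode
})

test_that("the transform is linear", {
  set.seed(8)
  x <- rnorm(500); y <- rnorm(500)
  a <- 2.5; b <- -1.25
  # same boundaries for a fair comparison: decompose the combined signal's
  # filters applied to each input
  mx <- suppressWarnings(ewt_decompose(x, K = 4))
  sx <- suppressWarnings(ewt_decompose(a * x, K = 4))
  expect_equal(sx$modes, a * mx$modes, tolerance = 1e-10)
  # additivity through a fixed bank
  bank <- mx$filter_bank
  apply_bank <- function(sig) {
    X <- stats::fft(sig)
    t(sapply(seq_len(ncol(bank$filters)), function(k) {
      Re(stats::fft(X * bank$filters[, k], inverse = TRUE)) / length(sig)
    }))
  }
  expect_equal(apply_bank(a * x + b * y),
               a * apply_bank(x) + b * apply_bank(y), tolerance = 1e-10)
})

test_that("smoothing-width tuning returns a candidate width", {
  x <- make_tone(10, 1, 250, 500)$samples + make_tone(40, 0.5, 250, 500)$samples
  w <- tune_smoothing(x, K = 2, widths = c(1, 2, 4))
  expect_true(w %in% c(1, 2, 4))
})
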