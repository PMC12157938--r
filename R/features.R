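#' Analytic signal via the frequency-domain Hilbert transformer
#'
#' Builds `z = x + i * H(x)` by zeroing negative frequencies and doubling
#' positive ones in the FFT; the instantaneous amplitude is `|z|` and the
#' instantaneous phase is the unwrapped argument of `z` (zero by convention
#' where `z = 0`).
#'
#' @param x numeric signal, length >= 8.
#' @return An object of class `analytic_series`: `z` (complex), `ia`
#'   (instantaneous amplitude), `phase` (unwrapped, radians).
#' @export
#' @examples
#' a <- analytic_signal(make_tone(15, 1, 250, 1250)$samples)
#' summary(a$ia[100:1150])
analytic_signal <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 8) stop("signal too short for the Hilbert transformer (need >= 8)")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  structure(
    list(z = z, ia = Mod(z), phase = unwrap_phase(Arg(z))),
    class = "analytic_series"
  )
}

#' Instantaneous frequency from an analytic series
#'
#' Discretizes the phase derivative by central differences on the unwrapped
#' phase (second-order accurate), with one-sided differences at the
#' endpoints; a forward-difference mode is available.
#'
#' @param a an [analytic_signal()] object.
#' @param fs sampling rate in Hz.
#' @param method `"central"` (default) or `"forward"`.
#' @return Instantaneous frequency in Hz, same length as the input.
#' @export
instantaneous_frequency <- function(a, fs, method = c("central", "forward")) {
  stopifnot(inherits(a, "analytic_series"), fs > 0)
  method <- match.arg(method)
  th <- a$phase
  n <- length(th)
  if (n < 3) stop("need at least 3 samples for instantaneous frequency")
  d <- numeric(n)
  if (method == "central") {
    d[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / 2
    d[1] <- th[2] - th[1]
    d[n] <- th[n] - th[n - 1]
  } else {
    d[1:(n - 1)] <- diff(th)
    d[n] <- d[n - 1]
  }
  d * fs / (2 * pi)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper: the signal is split into
#' overlapping segments, each windowed and transformed, and the one-sided
#' densities averaged. The integral of the returned density over frequency
#' equals the mean windowed signal power (Parseval), so for zero-mean white
#' noise it estimates the variance.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `min(256, length(x))`).
#' @param seg_overlap segment overlap fraction (default 0.5).
#' @return List with `freq` (Hz) and `psd` (one-sided density, power/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = min(256L, length(x)),
                      seg_overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0, seg_overlap >= 0, seg_overlap < 1)
  n <- length(x)
  if (seg_len > n) stop("segment longer than the signal")
  L <- as.integer(seg_len)
  step <- max(1L, as.integer(floor((1 - seg_overlap) * L)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)   # periodic Hann
  U <- sum(w^2)
  half <- floor(L / 2) + 1
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(half)]
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double interior bins (DC and, for even L, Nyquist excluded)
  interior <- 2:(half - if (L %% 2 == 0) 1 else 0)
  psd[interior] <- 2 * psd[interior]
  list(freq = (0:(half - 1)) * fs / L, psd = psd)
}

#' Pick the most task-sensitive EWT mode by spectral power
#'
#' For each mode the Welch PSD is computed and summed over frequencies above
#' 2 Hz (slow drifts excluded); the mode with the largest mass wins, ties
#' resolved toward the lowest index. An alternative criterion uses the
#' largest single PSD bin above 2 Hz.
#'
#' @param modes an [ewt_decompose()] object.
#' @param fs sampling rate in Hz.
#' @param criterion `"total"` (default) or `"maxbin"`.
#' @return Integer mode index (1-based).
#' @export
select_sensitive_mode <- function(modes, fs, criterion = c("total", "maxbin")) {
  stopifnot(inherits(modes, "ewt_modes"))
  criterion <- match.arg(criterion)
  score <- apply(modes$modes, 1, function(m) {
    p <- welch_psd(m, fs, seg_len = min(256L, length(m)))
    keep <- p$freq > 2
    if (!any(keep)) return(0)
    if (criterion == "total") sum(p$psd[keep]) else max(p$psd[keep])
  })
  which.max(score)
}

#' Higher-order statistics of a sample window
#'
#' The four per-window descriptors used as features: mean absolute deviation
#' `(1/n) sum |x_i - mean(x)|`; interquartile range `Q3 - Q1` where Q1/Q3 are
#' the medians of the lower/upper halves of the sorted data (the overall
#' median excluded from both halves when `n` is odd); skewness
#' `m3 / m2^(3/2)`; and non-excess kurtosis `m4 / m2^2` (Gaussian -> 3), both
#' with biased `1/n` central moments and no small-sample correction.
#'
#' @param x numeric vector.
#' @param degenerate for skewness/kurtosis on zero-variance input: `"error"`
#'   (default for the scalar functions) or `"zero"`.
#' @return `hos_features()` returns the named 4-vector
#'   `c(mad, iqr, skewness, kurtosis)`; the scalar functions return one value.
#' @export
#' @examples
#' hos_mad(c(1, 2, 3, 4))       # 1
#' hos_iqr(c(1, 2, 3, 4))       # 2
#' hos_kurtosis(c(-1, 1, -1, 1))  # 1
hos_mad <- function(x) {
  stopifnot(length(x) >= 1)
  mean(abs(x - mean(x)))
}

#' @rdname hos_mad
#' @export
hos_iqr <- function(x) {
  n <- length(x)
  if (n < 2) stop("IQR needs at least 2 values")
  s <- sort(x)
  lower <- s[seq_len(floor(n / 2))]
  upper <- s[seq.int(ceiling(n / 2) + 1L, n)]
  stats::median(upper) - stats::median(lower)
}

#' @rdname hos_mad
#' @export
hos_skewness <- function(x, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  n <- length(x)
  if (n < 2) stop("skewness needs at least 2 values")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= .Machine$double.xmin) {
    if (degenerate == "zero") return(0)
    stop("skewness undefined: zero variance")
  }
  mean(xc^3) / m2^1.5
}

#' @rdname hos_mad
#' @export
hos_kurtosis <- function(x, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  n <- length(x)
  if (n < 2) stop("kurtosis needs at least 2 values")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= .Machine$double.xmin) {
    if (degenerate == "zero") return(0)
    stop("kurtosis undefined: zero variance")
  }
  mean(xc^4) / m2^2
}

#' @rdname hos_mad
#' @export
hos_features <- function(x, degenerate = c("zero", "error")) {
  degenerate <- match.arg(degenerate)
  c(
    mad = hos_mad(x),
    iqr = hos_iqr(x),
    skewness = hos_skewness(x, degenerate),
    kurtosis = hos_kurtosis(x, degenerate)
  )
}

#' Time-domain band power of a window
#'
#' Mean squared sample value; applied to windows of the 8-25 Hz bandpassed
#' stream this is the classical mu/beta bandpower feature.
#'
#' @param w numeric window.
#' @return Scalar power.
#' @export
bandpower <- function(w) {
  if (length(w) == 0) stop("empty window")
  mean(w^2)
}
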