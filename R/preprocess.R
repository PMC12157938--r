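#' Design a digital Butterworth band filter
#'
#' Thin wrapper around [signal::butter()] producing the 5th-order bandstop
#' (mains notch, default edges 58-62 Hz) and bandpass (mu/beta band, 8-25 Hz)
#' designs used by the pipeline. A 50 Hz mains preset is available via
#' `edges = c(48, 52)`.
#'
#' @param kind `"bandstop"` or `"bandpass"`.
#' @param order filter order (the design order per band edge; default 5).
#' @param edges numeric length-2 vector `c(low, high)` in Hz, strictly inside
#'   `(0, fs/2)`.
#' @param fs sampling rate in Hz.
#' @return An object of class `filter_spec` carrying the transfer-function
#'   coefficients `b`, `a` and the design metadata.
#' @export
#' @examples
#' notch <- design_butterworth("bandstop", 5, c(58, 62), 250)
#' Mod(freq_response(notch, 60))
design_butterworth <- function(kind = c("bandstop", "bandpass"), order = 5,
                               edges, fs) {
  kind <- match.arg(kind)
  stopifnot(order >= 1, length(edges) == 2, fs > 0)
  if (!(edges[1] > 0 && edges[1] < edges[2] && edges[2] < fs / 2)) {
    stop(sprintf("band edges must satisfy 0 < %g < %g < fs/2 = %g",
                 edges[1], edges[2], fs / 2))
  }
  bt <- signal::butter(order, edges / (fs / 2),
                       type = if (kind == "bandstop") "stop" else "pass")
  structure(
    list(kind = kind, order = order, edges = edges, fs = fs,
         b = as.numeric(bt$b), a = as.numeric(bt$a)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s Butterworth, order %d, %g-%g Hz @ %g Hz\n",
              x$kind, x$order, x$edges[1], x$edges[2], x$fs))
  invisible(x)
}

#' Complex frequency response of a designed filter
#'
#' Evaluates the transfer function `H(e^{j 2 pi f / fs})` analytically from the
#' filter coefficients; used to verify stopband/passband behaviour.
#'
#' @param spec a [design_butterworth()] filter.
#' @param f frequencies in Hz.
#' @return Complex response, one value per frequency.
#' @export
freq_response <- function(spec, f) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- 2 * pi * f / spec$fs
  resp <- vapply(w, function(wi) {
    e <- exp(-1i * wi * (0:(max(length(spec$b), length(spec$a)) - 1)))
    num <- sum(spec$b * e[seq_along(spec$b)])
    den <- sum(spec$a * e[seq_along(spec$a)])
    num / den
  }, complex(1))
  resp
}

#' Apply a filter with zero net phase (forward-backward)
#'
#' Forward-backward application via [signal::filtfilt()] so the passband is
#' traversed with zero phase distortion -- important because instantaneous
#' phase/frequency are computed downstream. A causal single-pass mode is
#' available for streaming-style use.
#'
#' @param spec a [design_butterworth()] filter.
#' @param x numeric signal; must be longer than `3 * (2 * order + 1)` samples
#'   so the edge transients have room.
#' @param causal if `TRUE`, single forward pass ([signal::filter()]) instead.
#' @return Filtered signal, same length as `x`.
#' @export
apply_zero_phase <- function(spec, x, causal = FALSE) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x))
  need <- 3 * (2 * spec$order + 1)
  if (length(x) <= need) {
    stop(sprintf("signal too short to filter: need > %d samples, got %d",
                 need, length(x)))
  }
  if (causal) {
    as.numeric(signal::filter(spec$b, spec$a, x))
  } else {
    as.numeric(signal::filtfilt(spec$b, spec$a, x))
  }
}

#' Select and reorder channels of a trialset
#'
#' @param ts a [trialset()].
#' @param names channel labels to keep, in the requested order (e.g.
#'   `c("C3", "Cz", "C4")` for the central motor strip).
#' @return A [trialset()] restricted to `names`.
#' @export
select_channels <- function(ts, names) {
  stopifnot(inherits(ts, "trialset"))
  idx <- match(names, ts$channel_names)
  if (anyNA(idx)) {
    stop(sprintf("unknown channel(s): %s",
                 paste(names[is.na(idx)], collapse = ", ")))
  }
  trialset(ts$trials[, idx, , drop = FALSE], ts$gesture_labels,
           ts$subject_ids, ts$channel_names[idx], ts$fs, posture = ts$posture)
}

#' Plan sliding windows with fractional overlap
#'
#' The step is `round((1 - overlap) * window_len)` with halves rounded away
#' from zero, and the window count `floor((n - window_len) / step) + 1`.
#' With the pipeline defaults (1250-sample trials, 50-sample windows, 60%
#' overlap) this yields step 20 and 61 windows per trial and channel.
#'
#' @param n_samples trial length in samples.
#' @param window_len window length in samples.
#' @param overlap overlap fraction in `[0, 1)` (default 0.6).
#' @return An object of class `window_plan` with fields `window_len`, `step`,
#'   `n_windows`, `n_samples`.
#' @export
#' @examples
#' plan_windows(1250, 50, 0.6)
plan_windows <- function(n_samples, window_len, overlap = 0.6) {
  stopifnot(n_samples >= 1, window_len >= 1, overlap >= 0, overlap < 1)
  if (window_len > n_samples) {
    stop(sprintf("window_len = %d exceeds trial length %d",
                 window_len, n_samples))
  }
  step <- as.integer(round_half_away((1 - overlap) * window_len))
  step <- max(step, 1L)
  n_windows <- as.integer(floor((n_samples - window_len) / step) + 1)
  structure(
    list(window_len = as.integer(window_len), step = step,
         n_windows = n_windows, n_samples = as.integer(n_samples)),
    class = "window_plan"
  )
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan> %d windows of %d samples, step %d (trial %d)\n",
              x$n_windows, x$window_len, x$step, x$n_samples))
  invisible(x)
}

#' Segment a signal into the planned sliding windows
#'
#' Window `w` covers the half-open sample range
#' `[(w-1)*step, (w-1)*step + window_len)` (1-based rows, 0-based sample
#' positions).
#'
#' @param x numeric signal of length `plan$n_samples`.
#' @param plan a [plan_windows()] plan.
#' @return Numeric matrix `[n_windows x window_len]`.
#' @export
segment_signal <- function(x, plan) {
  stopifnot(inherits(plan, "window_plan"))
  if (length(x) != plan$n_samples) {
    stop(sprintf("plan was made for %d samples but signal has %d",
                 plan$n_samples, length(x)))
  }
  starts <- (seq_len(plan$n_windows) - 1L) * plan$step
  idx <- outer(starts, seq_len(plan$window_len), `+`)  # starts + 1..len
  matrix(x[idx], plan$n_windows, plan$window_len)
}
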