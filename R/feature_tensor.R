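#' Assemble classifier-ready feature tensors from a trial set
#'
#' Runs one of the two preprocessing variants end to end and stacks per-window
#' features into a 4-d array `[n_trials x n_windows x n_channels x n_features]`.
#'
#' All variants first remove the mains component with a zero-phase 5th-order
#' Butterworth bandstop (`notch`). Then:
#' \describe{
#'   \item{`bandpower`}{variant 1: zero-phase 8-25 Hz bandpass, sliding
#'     windows, mean squared value per window (1 feature).}
#'   \item{`raw_band`}{variant 1 without feature extraction: the windowed
#'     bandpassed samples themselves (`window_len` features).}
#'   \item{`hos_if`, `hos_ia`, `hos_if_ia`}{variant 2: per channel the trial
#'     is decomposed with the empirical wavelet transform (`K` modes), the
#'     most task-sensitive mode is selected by Welch-PSD power above 2 Hz,
#'     the mode is windowed, each window's analytic signal yields
#'     instantaneous frequency and/or amplitude, and the four higher-order
#'     statistics of each requested series are the features (4 or 8).}
#'   \item{`raw_mode`}{variant 2 without feature extraction: the windowed
#'     samples of the most sensitive mode (`window_len` features).}
#' }
#'
#' @param ts a [trialset()].
#' @param variant one of `"bandpower"`, `"hos_if"`, `"hos_ia"`, `"hos_if_ia"`,
#'   `"raw_band"`, `"raw_mode"`.
#' @param channels channel labels to use (default: all, in stored order).
#' @param window_len,overlap sliding-window parameters (defaults 50 samples,
#'   60% overlap: 61 windows on a 5 s trial at 250 Hz).
#' @param band bandpass edges in Hz for variant 1 (default `c(8, 25)`).
#' @param notch bandstop edges in Hz (default `c(58, 62)`).
#' @param K number of EWT modes for variant 2 (default 10).
#' @param smoothing EWT boundary-detection smoothing (bins).
#' @param if_method instantaneous-frequency discretization, see
#'   [instantaneous_frequency()].
#' @param mode_scope `"trial"` (default: pick the sensitive mode per trial and
#'   channel) or `"channel"` (majority vote across trials for a globally fixed
#'   mode per channel).
#' @return An object of class `feature_tensor`: `values` (4-d array),
#'   `feature_names`, `variant`, `channel_names`, `plan`, plus the trials'
#'   `gesture_labels` and `subject_ids` carried through.
#' @export
extract_features <- function(ts,
                             variant = c("hos_if_ia", "hos_if", "hos_ia",
                                         "bandpower", "raw_band", "raw_mode"),
                             channels = NULL, window_len = 50, overlap = 0.6,
                             band = c(8, 25), notch = c(58, 62), K = 10,
                             smoothing = 2,
                             if_method = "central",
                             mode_scope = c("trial", "channel")) {
  stopifnot(inherits(ts, "trialset"))
  variant <- match.arg(variant)
  mode_scope <- match.arg(mode_scope)
  if (!is.null(channels)) ts <- select_channels(ts, channels)
  d <- dim(ts$trials)
  n_trials <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  plan <- plan_windows(n_samp, window_len, overlap)
  fs <- ts$fs

  nf <- switch(variant,
    bandpower = 1L,
    hos_if = 4L, hos_ia = 4L, hos_if_ia = 8L,
    raw_band = plan$window_len, raw_mode = plan$window_len
  )
  feature_names <- switch(variant,
    bandpower = "bandpower",
    hos_if = paste0("if_", c("mad", "iqr", "skewness", "kurtosis")),
    hos_ia = paste0("ia_", c("mad", "iqr", "skewness", "kurtosis")),
    hos_if_ia = c(paste0("if_", c("mad", "iqr", "skewness", "kurtosis")),
                  paste0("ia_", c("mad", "iqr", "skewness", "kurtosis"))),
    raw_band = paste0("s", seq_len(plan$window_len)),
    raw_mode = paste0("s", seq_len(plan$window_len))
  )

  values <- array(0, c(n_trials, plan$n_windows, n_ch, nf))

  if (n_trials == 0) {
    return(structure(
      list(values = values, feature_names = feature_names, variant = variant,
           channel_names = ts$channel_names, plan = plan, fs = fs,
           gesture_labels = ts$gesture_labels, subject_ids = ts$subject_ids),
      class = "feature_tensor"
    ))
  }

  notch_f <- design_butterworth("bandstop", 5, notch, fs)
  band_f <- if (variant %in% c("bandpower", "raw_band")) {
    design_butterworth("bandpass", 5, band, fs)
  } else NULL

  use_ewt <- variant %in% c("hos_if", "hos_ia", "hos_if_ia", "raw_mode")

  # optional globally fixed sensitive mode per channel (majority over trials)
  fixed_mode <- NULL
  get_mode_signal <- function(x) {
    m <- suppressWarnings(ewt_decompose(x, K = K, smoothing = smoothing))
    list(modes = m, idx = select_sensitive_mode(m, fs))
  }
  if (use_ewt && mode_scope == "channel") {
    fixed_mode <- integer(n_ch)
    for (ch in seq_len(n_ch)) {
      votes <- vapply(seq_len(n_trials), function(i) {
        x <- apply_zero_phase(notch_f, ts$trials[i, ch, ])
        get_mode_signal(x)$idx
      }, integer(1))
      fixed_mode[ch] <- as.integer(names(which.max(table(votes))))
    }
  }

  for (i in seq_len(n_trials)) {
    for (ch in seq_len(n_ch)) {
      x <- apply_zero_phase(notch_f, ts$trials[i, ch, ])
      if (use_ewt) {
        dec <- get_mode_signal(x)
        idx <- if (is.null(fixed_mode)) dec$idx else
          min(fixed_mode[ch], nrow(dec$modes$modes))
        sig <- dec$modes$modes[idx, ]
      } else {
        sig <- apply_zero_phase(band_f, x)
      }
      wins <- segment_signal(sig, plan)
      if (variant == "bandpower") {
        values[i, , ch, 1] <- rowMeans(wins^2)
      } else if (variant %in% c("raw_band", "raw_mode")) {
        values[i, , ch, ] <- wins
      } else {
        for (w in seq_len(plan$n_windows)) {
          a <- analytic_signal(wins[w, ])
          feats <- numeric(0)
          if (variant %in% c("hos_if", "hos_if_ia")) {
            iff <- instantaneous_frequency(a, fs, method = if_method)
            feats <- c(feats, hos_features(iff, degenerate = "zero"))
          }
          if (variant %in% c("hos_ia", "hos_if_ia")) {
            feats <- c(feats, hos_features(a$ia, degenerate = "zero"))
          }
          values[i, w, ch, ] <- feats
        }
      }
    }
  }

  structure(
    list(values = values, feature_names = feature_names, variant = variant,
         channel_names = ts$channel_names, plan = plan, fs = fs,
         gesture_labels = ts$gesture_labels, subject_ids = ts$subject_ids),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<feature_tensor> %s: %d trials x %d windows x %d channels x %d features\n",
    x$variant, d[1], d[2], d[3], d[4]
  ))
  invisible(x)
}

# flatten for vector classifiers: [n_trials x (windows*channels*features)]
flatten_tensor <- function(ft) {
  d <- dim(ft$values)
  matrix(ft$values, d[1], prod(d[-1]))
}

# sequence view for the HNN: [n_trials, n_windows, channels*features]
sequence_tensor <- function(ft) {
  d <- dim(ft$values)
  array(ft$values, c(d[1], d[2], d[3] * d[4]))
}
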