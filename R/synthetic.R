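#' Pure-tone fixture with known instantaneous amplitude and frequency
#'
#' Generates `amp * cos(2*pi*freq*t + phase)` together with its closed-form
#' instantaneous amplitude (constant `amp`) and instantaneous frequency
#' (constant `freq`). These fixtures are the independent oracle for the
#' analytic-signal estimators.
#'
#' @param freq tone frequency in Hz; must lie strictly below the Nyquist
#'   frequency `fs/2`.
#' @param amp amplitude (signal units).
#' @param fs sampling rate in Hz.
#' @param n number of samples.
#' @param phase initial phase in radians.
#' @return An object of class `signal_fixture` with fields `samples`, `fs`,
#'   `truth_ia`, `truth_if`.
#' @export
#' @examples
#' fx <- make_tone(15, 1, 250, 1250)
#' range(fx$truth_if)
make_tone <- function(freq, amp = 1, fs, n, phase = 0) {
  stopifnot(fs > 0, n >= 1)
  if (freq <= 0 || freq >= fs / 2) {
    stop(sprintf("aliasing: freq = %g Hz must lie in (0, fs/2 = %g Hz)",
                 freq, fs / 2))
  }
  t <- (0:(n - 1)) / fs
  structure(
    list(
      samples = amp * cos(2 * pi * freq * t + phase),
      fs = fs,
      truth_ia = rep(abs(amp), n),
      truth_if = rep(freq, n)
    ),
    class = "signal_fixture"
  )
}

#' Linear-chirp fixture with known instantaneous frequency ramp
#'
#' Constant-amplitude linear chirp sweeping `f0` to `f1` over the signal
#' duration; the instantaneous frequency truth is the linear ramp
#' `f0 + (f1 - f0) * t / T` hitting `f1` exactly at the final sample.
#'
#' @param f0,f1 start/end frequencies in Hz, strictly inside `(0, fs/2)`.
#' @param amp amplitude.
#' @param fs sampling rate in Hz.
#' @param n number of samples (`n >= 2`).
#' @return A `signal_fixture`; see [make_tone()].
#' @export
make_chirp <- function(f0, f1, amp = 1, fs, n) {
  stopifnot(fs > 0, n >= 2)
  for (f in c(f0, f1)) {
    if (f <= 0 || f >= fs / 2) {
      stop(sprintf("aliasing: frequency %g Hz must lie in (0, fs/2 = %g Hz)",
                   f, fs / 2))
    }
  }
  t <- (0:(n - 1)) / fs
  T <- (n - 1) / fs
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * T))
  structure(
    list(
      samples = amp * cos(phase),
      fs = fs,
      truth_ia = rep(abs(amp), n),
      truth_if = f0 + (f1 - f0) * t / T
    ),
    class = "signal_fixture"
  )
}

# Fixed gesture patterns: channel subset, mu/beta amplitude gains,
# mu/beta center-frequency offsets (Hz) and FM depth. Seven distinct patterns
# guarantee learnability once the class-separation scale is large enough.
gesture_patterns <- function(n_channels) {
  subsets8 <- list(
    c("C3", "Cz", "C4"),
    c("F3", "C3", "P3"),
    c("F4", "C4", "P4"),
    c("Cz", "Pz"),
    c("F3", "F4", "Cz"),
    c("P3", "Pz", "P4"),
    c("C3", "C4")
  )
  idx8 <- lapply(subsets8, function(s) match(s, default_channels()))
  pats <- list()
  for (g in 1:7) {
    if (n_channels == 8) {
      ch <- idx8[[g]]
    } else {
      ch <- unique(((g - 1) + 0:2) %% n_channels) + 1
    }
    pats[[g]] <- list(
      channels = ch,
      mu_gain = c(1.2, 1.0, 1.0, 1.1, 0.9, 1.0, 1.1)[g],
      beta_gain = c(0.6, 1.0, 0.8, 0.5, 1.1, 0.9, 0.7)[g],
      mu_off = c(-1.5, -1.0, -0.5, 0, 0.5, 1.0, 1.5)[g],
      beta_off = c(3, -3, 2, -2, 1, -1, 0)[g],
      fm_depth = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5)[g]
    )
  }
  pats
}

default_channels <- function() c("F3", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")

#' Generate a synthetic motor-execution EEG trial set
#'
#' Emulates the shape and statistical structure of an 8-electrode, 250 Hz
#' motor-execution recording: each 5 s trial is pink (`1/f^alpha`) background
#' noise plus a 60 Hz line component plus a common sensorimotor rhythm (mu at
#' 10 Hz, beta at 20 Hz, randomly amplitude-modulated, identical in
#' distribution across gestures), plus a gesture-specific AM-FM component.
#' Each of the seven gestures imposes its own channel subset, mu/beta
#' amplitude gains, center-frequency offsets and FM depth; the whole
#' gesture-specific term is scaled by `class_separation`, so at
#' `class_separation = 0` the gesture-conditional distributions are identical
#' and no classifier can beat chance.
#'
#' @param n_subjects,n_gestures,n_reps protocol counts; the full protocol is
#'   33 subjects x 7 gestures x 6 repetitions = 1386 trials. `n_gestures`
#'   cannot exceed the 7 shipped gesture patterns.
#' @param fs sampling rate (Hz).
#' @param duration trial length in seconds; `duration * fs` must be integral.
#' @param n_channels number of electrodes (default 8: F3 F4 C3 Cz C4 P3 Pz P4).
#' @param class_separation nonnegative effect-size scale of the
#'   gesture-specific mu/beta modulation.
#' @param line_amp amplitude of the 60 Hz mains component.
#' @param noise_exponent pink-noise `1/f^alpha` exponent.
#' @param rhythm_amp amplitude of the common (gesture-independent)
#'   sensorimotor rhythm.
#' @param seed integer seed; the same seed yields a bit-identical trial set.
#' @return A [trialset()]; the last two repetitions carry a `"standing"`
#'   posture flag (recorded, not modeled).
#' @export
#' @examples
#' ts <- generate_trialset(n_subjects = 1, n_reps = 1, seed = 1)
#' dim(ts)
generate_trialset <- function(n_subjects = 33, n_gestures = 7, n_reps = 6,
                              fs = 250, duration = 5, n_channels = 8,
                              class_separation = 1, line_amp = 1,
                              noise_exponent = 1, rhythm_amp = 2, seed = 1) {
  stopifnot(n_subjects >= 1, n_gestures >= 1, n_reps >= 1,
            fs > 0, duration > 0, n_channels >= 1, class_separation >= 0)
  n_samples <- duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration * fs must be an integral number of samples")
  }
  n_samples <- as.integer(round(n_samples))
  pats <- gesture_patterns(n_channels)
  if (n_gestures > length(pats)) {
    stop(sprintf("n_gestures = %d exceeds the %d shipped gesture patterns",
                 n_gestures, length(pats)))
  }
  channel_names <- if (n_channels == 8) default_channels() else
    paste0("ch", seq_len(n_channels))

  n_trials <- n_subjects * n_gestures * n_reps
  trials <- array(0, c(n_trials, n_channels, n_samples))
  labels <- integer(n_trials)
  subjects <- integer(n_trials)
  posture <- character(n_trials)
  t <- (0:(n_samples - 1)) / fs

  with_local_seed(seed, {
    i <- 0L
    for (s in seq_len(n_subjects)) {
      for (g in seq_len(n_gestures)) {
        for (r in seq_len(n_reps)) {
          i <- i + 1L
          labels[i] <- g - 1L
          subjects[i] <- s
          posture[i] <- if (n_reps >= 3 && r > n_reps - 2) "standing" else "sitting"
          x <- matrix(0, n_channels, n_samples)
          # background: pink noise per channel + line component
          for (ch in seq_len(n_channels)) {
            x[ch, ] <- pink_noise(n_samples, noise_exponent)
          }
          if (line_amp > 0) {
            line_phase <- stats::runif(1, 0, 2 * pi)
            x <- x + matrix(line_amp * sin(2 * pi * 60 * t + line_phase),
                            n_channels, n_samples, byrow = TRUE)
          }
          # common sensorimotor rhythm, identical in law for every gesture
          for (ch in seq_len(n_channels)) {
            env <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.2, 0.8) * t +
                                   stats::runif(1, 0, 2 * pi))
            x[ch, ] <- x[ch, ] +
              rhythm_amp * env * cos(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) +
              0.5 * rhythm_amp * env * cos(2 * pi * 20 * t + stats::runif(1, 0, 2 * pi))
          }
          # gesture-specific AM-FM term, scaled by class_separation
          if (class_separation > 0) {
            p <- pats[[g]]
            f_mu <- 10 + p$mu_off
            f_beta <- 20 + p$beta_off
            for (ch in p$channels) {
              envg <- 1 + 0.4 * sin(2 * pi * stats::runif(1, 0.3, 1) * t +
                                      stats::runif(1, 0, 2 * pi))
              fm <- p$fm_depth * sin(2 * pi * 1.5 * t + stats::runif(1, 0, 2 * pi))
              ph_mu <- 2 * pi * f_mu * t + (p$fm_depth / 1.5) * -cos(2 * pi * 1.5 * t)
              x[ch, ] <- x[ch, ] + class_separation * (
                p$mu_gain * envg * cos(ph_mu + stats::runif(1, 0, 2 * pi)) +
                p$beta_gain * envg * cos(2 * pi * f_beta * t +
                                           cumsum(2 * pi * fm / fs) +
                                           stats::runif(1, 0, 2 * pi))
              )
            }
          }
          trials[i, , ] <- x
        }
      }
    }
  })

  trialset(trials, labels, subjects, channel_names, fs, posture = posture)
}
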