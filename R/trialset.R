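#' Labeled set of fixed-length multichannel EEG trials
#'
#' A `trialset` bundles a 3-d numeric array of trials with gesture labels,
#' subject identifiers, channel names and the sampling rate. It is the common
#' container passed between the generator, preprocessing, feature extraction
#' and the evaluation harness.
#'
#' @param trials numeric array `[n_trials x n_channels x n_samples]`.
#' @param gesture_labels integer vector, one label per trial (`0 .. G-1`).
#' @param subject_ids integer vector, one subject id per trial.
#' @param channel_names character vector of channel labels (10-20 names for
#'   the default montage).
#' @param fs sampling rate in Hz.
#' @param posture optional character vector per trial (e.g. `"sitting"` /
#'   `"standing"`); recorded but not modeled.
#'
#' @return An object of class `trialset`.
#' @export
trialset <- function(trials, gesture_labels, subject_ids, channel_names, fs,
                     posture = NULL) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  n <- dim(trials)[1]
  if (length(gesture_labels) != n || length(subject_ids) != n) {
    stop("labels and subject ids must have one entry per trial")
  }
  if (length(channel_names) != dim(trials)[2]) {
    stop("channel_names must match the channel dimension")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (!is.null(posture) && length(posture) != n) {
    stop("posture must have one entry per trial")
  }
  structure(
    list(
      trials = trials,
      gesture_labels = as.integer(gesture_labels),
      subject_ids = as.integer(subject_ids),
      channel_names = as.character(channel_names),
      fs = fs,
      posture = posture
    ),
    class = "trialset"
  )
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<trialset> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  cat(sprintf(
    "  gestures: %s\n  subjects: %d\n",
    paste(sort(unique(x$gesture_labels)), collapse = " "),
    length(unique(x$subject_ids))
  ))
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$trials)

#' Subset a trialset by trial index
#'
#' @param x a [trialset()].
#' @param i trial indices to keep.
#' @param ... ignored.
#' @return A `trialset` with the selected trials.
#' @export
`[.trialset` <- function(x, i, ...) {
  trialset(
    x$trials[i, , , drop = FALSE],
    x$gesture_labels[i],
    x$subject_ids[i],
    x$channel_names,
    x$fs,
    posture = if (!is.null(x$posture)) x$posture[i]
  )
}

#' Write / read a trialset as a plain-text directory container
#'
#' Each trial is stored as one delimited text file (`trial_0001.csv`, ...)
#' with one column per channel and a header row of channel names; labels,
#' subject ids, posture flags, channel names and the sampling rate live in a
#' JSON sidecar `meta.json`. The format is deliberately tool-agnostic.
#'
#' @param ts a [trialset()].
#' @param dir directory to create/populate.
#' @return `write_trialset` returns `dir` invisibly; `read_trialset` returns a
#'   [trialset()].
#' @export
write_trialset <- function(ts, dir) {
  stopifnot(inherits(ts, "trialset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(ts$trials)[1]
  for (i in seq_len(n)) {
    m <- t(ts$trials[i, , ])           # samples x channels
    colnames(m) <- ts$channel_names
    utils::write.csv(m, file.path(dir, sprintf("trial_%04d.csv", i)),
                     row.names = FALSE)
  }
  meta <- list(
    n_trials = n,
    gesture_labels = ts$gesture_labels,
    subject_ids = ts$subject_ids,
    channel_names = ts$channel_names,
    fs = ts$fs,
    posture = ts$posture
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trialset
#' @param dir directory previously written by `write_trialset`.
#' @export
read_trialset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- meta$n_trials
  first <- utils::read.csv(file.path(dir, "trial_0001.csv"), check.names = FALSE)
  arr <- array(NA_real_, c(n, ncol(first), nrow(first)))
  for (i in seq_len(n)) {
    m <- utils::read.csv(file.path(dir, sprintf("trial_%04d.csv", i)),
                         check.names = FALSE)
    arr[i, , ] <- t(as.matrix(m))
  }
  trialset(arr, meta$gesture_labels, meta$subject_ids, meta$channel_names,
           meta$fs, posture = meta$posture)
}
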