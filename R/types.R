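#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channel x sample, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel row.
#' @param t0 Time of the first sample in seconds relative to trial onset.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, t0 = 0) {
  stopifnot(is.matrix(data), fs > 0,
            length(channel_labels) == nrow(data))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 t0 = t0),
            class = "eeg_recording")
}

#' Epoched trial set
#'
#' @param trials Numeric array, trial x channel x sample, microvolts.
#' @param labels Character vector of per-trial classes, `"static"` or
#'   `"moving"`.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel labels matching the second dimension.
#' @param window Two-element numeric, epoch window in seconds relative to
#'   imagery onset; `diff(window) * fs` must equal the sample dimension.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, fs, channel_labels,
                      window = c(0, dim(trials)[3] / fs)) {
  stopifnot(length(dim(trials)) == 3,
            length(labels) == dim(trials)[1],
            all(labels %in% c("static", "moving")),
            length(channel_labels) == dim(trials)[2],
            abs(diff(window) * fs - dim(trials)[3]) < 1e-6)
  structure(list(trials = trials, labels = labels, fs = fs,
                 channel_labels = channel_labels, window = window),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d trials (%s), %d channels, %d samples @ %g Hz\n",
              dim(x$trials)[1],
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", "),
              dim(x$trials)[2], dim(x$trials)[3], x$fs))
  invisible(x)
}

# extract one trial as channel x sample matrix with labels
trial_matrix <- function(ts, k) {
  m <- ts$trials[k, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  rownames(m) <- ts$channel_labels
  m
}
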