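# Signal carriers: continuous multichannel recordings and stimulus-locked
# epoch sets. These stay as lightweight S3 records (channel x sample and
# trial x channel x sample arrays are not tabular); every derived summary
# is returned as a tibble.

#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel labels, one per
#'   row of `data`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate (Hz)", call. = FALSE)
  }
  fs <- as.numeric(fs)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row is required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (anyNA(data)) stop("recording contains missing samples", call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

# Extract one channel as a numeric vector, with a clear error.
channel_series <- function(rec, electrode) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(electrode, rec$channel_labels)
  if (is.na(idx)) {
    stop("channel not found: ", electrode, " (have: ",
         paste(rec$channel_labels, collapse = ", "), ")", call. = FALSE)
  }
  rec$data[idx, ]
}

#' Stimulus-locked epoch set
#'
#' @param data Numeric array, trials x channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param t0_index 1-based sample index of stimulus onset within each epoch.
#' @param labels Per-trial condition labels.
#' @param channel_labels Channel labels, one per array slice.
#' @return An object of class `eeg_epochs` with an onset-relative `times`
#'   axis in milliseconds (`times[t0_index] == 0`).
#' @export
eeg_epochs <- function(data, fs, t0_index, labels, channel_labels) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a trials x channels x samples array", call. = FALSE)
  }
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > dim(data)[3L]) {
    stop("`t0_index` outside the epoch", call. = FALSE)
  }
  if (length(labels) != dim(data)[1L]) {
    stop("one condition label per trial is required", call. = FALSE)
  }
  if (length(channel_labels) != dim(data)[2L]) {
    stop("one channel label per channel is required", call. = FALSE)
  }
  fs <- as.numeric(fs)
  times <- (seq_len(dim(data)[3L]) - t0_index) * 1000 / fs
  structure(
    list(data = data, fs = fs, t0_index = t0_index,
         labels = as.character(labels),
         channel_labels = as.character(channel_labels), times = times),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
    d[1L], d[2L], d[3L], x$fs
  ))
  cat(sprintf("window: [%g, %g] ms around onset (t0_index = %d)\n",
              min(x$times), max(x$times), x$t0_index))
  cat("conditions:",
      paste(sprintf("%s (%d)", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Keep the trials of one condition
#'
#' @param epochs An [eeg_epochs] object.
#' @param label Condition label to keep.
#' @return An [eeg_epochs] object with only the matching trials.
#' @export
filter_epochs <- function(epochs, label) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- which(epochs$labels == label)
  if (length(keep) == 0L) {
    stop("no trials with label: ", label, call. = FALSE)
  }
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$t0_index,
             epochs$labels[keep], epochs$channel_labels)
}

# trials x samples matrix for one electrode.
epoch_channel_matrix <- function(epochs, electrode) {
  idx <- match(electrode, epochs$channel_labels)
  if (is.na(idx)) {
    stop("channel not found: ", electrode, call. = FALSE)
  }
  m <- epochs$data[, idx, , drop = FALSE]
  dim(m) <- dim(m)[c(1L, 3L)]
  m
}
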