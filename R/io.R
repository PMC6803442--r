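# On-disk interchange: continuous recordings as a little-endian float64
# sample matrix with a JSON sidecar, event tables as TSV, epoch sets as a
# binary array with embedded metadata.

#' Write / read a continuous recording
#'
#' `write_recording()` stores the sample matrix as little-endian float64
#' in `<prefix>.dat` (channel-major: channel 1's samples, then channel
#' 2's, ...) with a JSON sidecar `<prefix>.json` holding the sampling
#' rate, channel labels and dimensions. `read_recording()` inverts it.
#'
#' @param rec An [eeg_recording].
#' @param prefix Path prefix (without extension).
#' @return `write_recording()` the prefix, invisibly; `read_recording()`
#'   an [eeg_recording].
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         n_channels = nrow(rec$data), n_samples = ncol(rec$data),
         dtype = "float64", byte_order = "little"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
               size = 8L, endian = "little")
  data <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  eeg_recording(data, meta$fs, meta$channel_labels)
}

#' Write / read an event table
#'
#' Tab-separated columns `onset_sample`, `label`, `rt_ms` (empty for
#' trials without a response).
#'
#' @param events Tibble with `onset_sample`, `label`, optional `rt_ms`.
#' @param path TSV file path.
#' @export
write_events <- function(events, path) {
  if (!"rt_ms" %in% names(events)) events$rt_ms <- NA_real_
  readr::write_tsv(events[, c("onset_sample", "label", "rt_ms")], path,
                   na = "")
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    onset_sample = readr::col_integer(),
    label = readr::col_character(),
    rt_ms = readr::col_double()
  ))
}

#' Write / read an epoch set
#'
#' Single-prefix container: `<prefix>.dat` holds the trials x channels x
#' samples array (little-endian float64, R array order), `<prefix>.json`
#' the metadata (fs, onset index, labels, channels).
#'
#' @param epochs An [eeg_epochs].
#' @param prefix Path prefix.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(fs = epochs$fs, t0_index = epochs$t0_index,
         labels = epochs$labels, channel_labels = epochs$channel_labels,
         dim = dim(epochs$data), dtype = "float64", byte_order = "little"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = prod(meta$dim), size = 8L,
               endian = "little")
  eeg_epochs(array(x, dim = meta$dim), meta$fs, meta$t0_index,
             meta$labels, meta$channel_labels)
}
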