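# Broadband / narrowband zero-phase FIR filtering, stimulus-locked
# epoching, and condition-balanced trial selection.

# Windowed (Hamming) linear-phase FIR band-pass kernel with explicit
# transition zones at each band edge. Order is the smallest even integer
# >= 3 cycles of the low cut-off, giving an odd, symmetric tap vector
# (type-I linear phase).
design_bandpass <- function(fs, low, high, transition_fraction) {
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  }
  if (transition_fraction <= 0) {
    stop("`transition_fraction` must be positive", call. = FALSE)
  }
  tb <- transition_fraction * (high - low)
  f_lo_stop <- max(0, low - tb)
  f_hi_stop <- min(nyq, high + tb)
  # long enough for both three cycles of the low cut-off and the Hamming
  # transition width (~3.3 fs / tb), so the passband actually reaches unity
  order <- 2L * ceiling(max(3 * fs / low, 3.3 * fs / tb) / 2)
  grid <- c(f_lo_stop, low, high, f_hi_stop) / nyq
  if (f_lo_stop <= 0) {
    f <- c(0, grid[2:4], 1)
    m <- c(0, 1, 1, 0, 0)
  } else if (f_hi_stop >= nyq) {
    f <- c(0, grid[1:3], 1)
    m <- c(0, 0, 1, 1, 1)
  } else {
    f <- c(0, grid, 1)
    m <- c(0, 0, 1, 1, 0, 0)
  }
  grid_n <- max(512L, 2L^ceiling(log2(order + 1L)))
  as.numeric(signal::fir2(order, f, m, grid_n = grid_n))
}

#' Zero-phase FIR band-pass filter
#'
#' Band-pass filters every channel of a continuous recording with a
#' Hamming-windowed linear-phase FIR kernel, applied forward and backward
#' (zero net phase, so onset-locked latencies are not biased). Transition
#' zones of `transition_fraction` times the band width are placed at each
#' band edge; the kernel order is three cycles of the low cut-off.
#'
#' @param rec An [eeg_recording].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param transition_fraction Transition-zone width per edge as a fraction
#'   of the band width (default 0.15).
#' @return A filtered [eeg_recording] of identical shape.
#' @export
fir_bandpass <- function(rec, low, high, transition_fraction = 0.15) {
  stopifnot(inherits(rec, "eeg_recording"))
  # forward-backward application of the symmetric kernel equals a single
  # zero-phase convolution with its autocorrelation (|B(f)|^2 response)
  ck <- cached_combined_kernel(rec$fs, low, high, transition_fraction)
  k <- length(ck)
  out <- rec$data
  n <- ncol(out)
  pad <- min(n - 1L, 3L * k %/% 2L)
  m <- stats::nextn(n + 2L * pad + k - 1L, c(2L, 3L, 5L))
  kf <- cached_kernel_fft(ck, m, rec$fs, low, high, transition_fraction)
  half <- (k - 1L) %/% 2L
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    xp <- c(2 * x[1L] - x[seq(pad + 1L, 2L)],
            x,
            2 * x[n] - x[seq(n - 1L, n - pad)])
    y <- Re(stats::fft(stats::fft(c(xp, numeric(m - length(xp)))) * kf,
                       inverse = TRUE)) / m
    out[ch, ] <- y[(half + pad + 1L):(half + pad + n)]
  }
  eeg_recording(out, rec$fs, rec$channel_labels)
}

# Kernel caches: filters are re-designed constantly across subjects.
.kernel_cache <- new.env(parent = emptyenv())

cached_combined_kernel <- function(fs, low, high, tf) {
  key <- paste("ck", fs, low, high, tf, sep = "|")
  ck <- .kernel_cache[[key]]
  if (is.null(ck)) {
    b <- design_bandpass(fs, low, high, tf)
    ck <- stats::convolve(b, b, type = "open")  # b * rev(b): autocorrelation
    .kernel_cache[[key]] <- ck
  }
  ck
}

cached_kernel_fft <- function(ck, m, fs, low, high, tf) {
  key <- paste("kf", fs, low, high, tf, m, sep = "|")
  kf <- .kernel_cache[[key]]
  if (is.null(kf)) {
    kf <- stats::fft(c(ck, numeric(m - length(ck))))
    .kernel_cache[[key]] <- kf
  }
  kf
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Epochs span `[tmin, tmax)` milliseconds around each event onset, with
#' the onset sample belonging to the post-stimulus side
#' (`t0_index = round(-tmin * fs / 1000) + 1`). No baseline correction is
#' applied. Events too close to a recording edge are dropped with a
#' warning.
#'
#' @param rec An [eeg_recording].
#' @param events Event table: a data frame with columns `onset_sample`
#'   (1-based), `label`, and optionally `rt_ms`.
#' @param tmin,tmax Epoch limits in ms relative to onset; `tmin < 0 < tmax`.
#' @return An [eeg_epochs] object; trials keep event order.
#' @export
epoch_recording <- function(rec, events, tmin, tmax) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(c("onset_sample", "label") %in% names(events))) {
    stop("`events` needs columns onset_sample and label", call. = FALSE)
  }
  if (!(tmin < 0 && tmax > 0)) stop("need tmin < 0 < tmax", call. = FALSE)
  fs <- rec$fs
  n_pre <- round(-tmin * fs / 1000)
  n_post <- round(tmax * fs / 1000)
  len <- n_pre + n_post                 # [tmin, tmax): tmax sample excluded
  n_samp <- ncol(rec$data)
  onset <- as.integer(events$onset_sample)
  first <- onset - n_pre
  last <- onset + n_post - 1L
  ok <- first >= 1L & last <= n_samp
  if (!all(ok)) {
    warning(sum(!ok), " event(s) too close to a recording edge were dropped",
            call. = FALSE)
  }
  if (!any(ok)) stop("all events fell outside the recording", call. = FALSE)
  onset <- onset[ok]
  out <- array(0, dim = c(length(onset), nrow(rec$data), len))
  for (i in seq_along(onset)) {
    out[i, , ] <- rec$data[, (onset[i] - n_pre):(onset[i] + n_post - 1L)]
  }
  eeg_epochs(out, fs, t0_index = n_pre + 1L,
             labels = events$label[ok], channel_labels = rec$channel_labels)
}

#' Randomly subsample trials of one condition
#'
#' Draws `n` trials of the given condition uniformly without replacement
#' (deterministic for a fixed seed) and discards all other trials. The
#' surviving trials keep their original order and their data bit-exactly.
#'
#' @param epochs An [eeg_epochs] object.
#' @param label Condition to sample from.
#' @param n Number of trials to keep.
#' @param seed Integer RNG seed.
#' @return An [eeg_epochs] object with `n` trials.
#' @export
subsample_trials <- function(epochs, label, n, seed) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$labels == label)
  if (n > length(idx)) {
    stop("requested ", n, " trials but only ", length(idx),
         " with label '", label, "' are available", call. = FALSE)
  }
  keep <- sort(withr::with_seed(as.integer(seed), sample(idx, n)))
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$fs, epochs$t0_index,
             epochs$labels[keep], epochs$channel_labels)
}
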