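# Analytic-signal machinery: time-domain peak frequency (instantaneous
# frequency of the band-limited signal), instantaneous power, and the
# resting-state PF / CV / power summary.

#' Instantaneous frequency of a band-limited series
#'
#' The peak frequency of a narrow-band signal is tracked in the time
#' domain: the analytic phase is unwrapped, its first difference scaled to
#' Hz (`fs / 2pi` times the phase increment; the first value is replicated
#' to preserve length), and a sliding median of length `median_order + 1`
#' removes phase-slip spikes. Values are not clipped to the band unless
#' `clip_band` is supplied.
#'
#' @param x Numeric vector, already band-pass filtered.
#' @param fs Sampling rate in Hz.
#' @param median_order Median filter order; the window holds
#'   `median_order + 1` samples (default 10). `0` disables filtering.
#' @param clip_band Optional `c(low, high)` in Hz; if supplied, the series
#'   is clipped into the band after median filtering (off by default).
#' @return Numeric vector of instantaneous frequency in Hz, same length as
#'   `x`.
#' @export
instantaneous_frequency <- function(x, fs, median_order = 10L,
                                    clip_band = NULL) {
  if (all(x == 0)) {
    stop("all-zero input: instantaneous phase is undefined", call. = FALSE)
  }
  if (median_order < 0L) stop("`median_order` must be >= 0", call. = FALSE)
  phase <- unwrap_phase(Arg(analytic_signal(x)))
  f <- fs / (2 * pi) * diff(phase)
  f <- c(f[1L], f)
  if (median_order > 0L) f <- sliding_median(f, median_order + 1L)
  if (!is.null(clip_band)) f <- pmin(pmax(f, clip_band[1L]), clip_band[2L])
  f
}

#' Instantaneous power of a band-limited series
#'
#' Squared modulus of the analytic signal, i.e. the squared envelope, in
#' microvolt^2 for microvolt input.
#'
#' @param x Numeric vector, already band-pass filtered.
#' @return Non-negative numeric vector, same length as `x`.
#' @export
instantaneous_power <- function(x) {
  Mod(analytic_signal(x))^2
}

#' Summary statistics of a peak-frequency series
#'
#' Mean and coefficient of variation (sample SD / mean) of an
#' instantaneous-frequency series; the dispersion measure used to
#' quantify resting peak-frequency stability.
#'
#' @param pf Numeric vector of instantaneous frequency (Hz).
#' @return One-row tibble with `mean_pf` and `cv`.
#' @export
pf_stats <- function(pf) {
  mu <- mean(pf)
  if (mu == 0) stop("mean peak frequency is zero; CV undefined", call. = FALSE)
  tibble::tibble(mean_pf = mu, cv = stats::sd(pf) / mu)
}

#' Resting-state peak frequency, CV, and band power at one electrode
#'
#' Band-passes one channel (15% transition zones by default), tracks the
#' instantaneous (peak) frequency and instantaneous power, and summarises
#' the recording by the time-mean peak frequency, its coefficient of
#' variation (sample SD over mean), and the time-mean power. Edge samples
#' (one filter order at each end) are excluded from all means. When the
#' recording is longer than `max_samples` it is truncated first so that
#' every subject contributes the same length (85,000 samples for a 3-min
#' rest at 500 Hz).
#'
#' @param rec An [eeg_recording] (broadband or raw rest data).
#' @param electrode Channel label, e.g. `"Fz"` or `"Pz"`.
#' @param band `c(low, high)` in Hz.
#' @param transition_fraction Passed to [fir_bandpass()].
#' @param median_order Passed to [instantaneous_frequency()].
#' @param max_samples Truncate the recording to this many samples when it
#'   is longer (default 85000); `Inf` disables truncation.
#' @return One-row tibble: `electrode`, `band_low`, `band_high`,
#'   `mean_pf` (Hz), `cv`, `mean_power` (uV^2), `n_samples`.
#' @export
resting_summary <- function(rec, electrode, band,
                            transition_fraction = 0.15,
                            median_order = 10L,
                            max_samples = 85000L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!electrode %in% rec$channel_labels) {
    stop("channel not found: ", electrode, call. = FALSE)
  }
  n <- ncol(rec$data)
  keep_n <- if (is.finite(max_samples)) min(n, max_samples) else n
  rec <- eeg_recording(rec$data[electrode, seq_len(keep_n), drop = FALSE],
                       rec$fs, electrode)
  filtered <- fir_bandpass(rec, band[1L], band[2L], transition_fraction)
  x <- channel_series(filtered, electrode)
  order <- length(design_bandpass(rec$fs, band[1L], band[2L],
                                  transition_fraction)) - 1L
  keep <- seq.int(order + 1L, length(x) - order)
  pf <- instantaneous_frequency(x, rec$fs, median_order)[keep]
  pw <- instantaneous_power(x)[keep]
  stats <- pf_stats(pf)
  tibble::tibble(
    electrode = electrode,
    band_low = band[1L], band_high = band[2L],
    mean_pf = stats$mean_pf, cv = stats$cv,
    mean_power = mean(pw),
    n_samples = length(keep)
  )
}
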