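# Task-locked frequency sliding (FS) and power sliding (PS): per-trial
# instantaneous frequency / power, trial-averaged, expressed as percent
# change from stimulus onset, with fixed AUC windows per band.

#' Fixed AUC windows for frequency and power sliding
#'
#' The 100-ms windows in which FS/PS area under the curve is read out:
#' alpha FS 376-476 ms, alpha PS 150-250 ms, theta FS 400-500 ms,
#' theta PS 166-266 ms. Treated as fixed constants of the analysis.
#'
#' @return Tibble with columns `band`, `measure`, `t_start`, `t_end` (ms).
#' @export
auc_windows <- function() {
  tibble::tribble(
    ~band,   ~measure, ~t_start, ~t_end,
    "alpha", "fs",     376,      476,
    "alpha", "ps",     150,      250,
    "theta", "fs",     400,      500,
    "theta", "ps",     166,      266
  )
}

#' Trial-averaged frequency- and power-sliding curves
#'
#' Per trial, the instantaneous frequency (median-filtered analytic phase
#' derivative) and instantaneous power (squared envelope) are computed on
#' epochs cut from narrow-band filtered data; each is averaged across
#' trials at every timepoint, and the mean curves converted to percent
#' change relative to stimulus onset:
#' `pc(t) = (m(t) - m(0)) / m(0) * 100`. The raw mean curves (Hz, uV^2)
#' are kept alongside for absolute-value AUC readouts.
#'
#' @param epochs An [eeg_epochs] object whose data were band-passed in
#'   `band` *before* epoching; one condition (use [filter_epochs()]).
#' @param band `c(low, high)` in Hz (labels: theta 4-8 at Fz, alpha 7-13 at
#'   Pz for task data).
#' @param electrode Channel label.
#' @param median_order Median filter order for the per-trial frequency
#'   series (default 10).
#' @param per_trial_percent If `TRUE`, percent change is taken per trial
#'   before averaging instead of on the trial-mean curves (default
#'   `FALSE`: mean first, then percent change).
#' @return A `sliding_curves` object: tibble `curve` (`time_ms`, `fs_pct`,
#'   `ps_pct`, `fs_raw`, `ps_raw`) plus `band`, `electrode`, `condition`,
#'   `n_trials`.
#' @export
sliding_curves <- function(epochs, band, electrode, median_order = 10L,
                           per_trial_percent = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  m <- epoch_channel_matrix(epochs, electrode)
  n_tr <- nrow(m)
  if (n_tr < 2L) stop("need >= 2 trials", call. = FALSE)
  deriv <- analytic_epochs(m, epochs$fs, median_order)
  fs_mat <- deriv$freq
  ps_mat <- deriv$power
  t0 <- epochs$t0_index
  eps <- 1e-12
  if (per_trial_percent) {
    if (any(abs(ps_mat[, t0]) < eps)) {
      stop("per-trial power at onset below epsilon; percent change undefined",
           call. = FALSE)
    }
    fs_pct <- colMeans((fs_mat - fs_mat[, t0]) / fs_mat[, t0] * 100)
    ps_pct <- colMeans((ps_mat - ps_mat[, t0]) / ps_mat[, t0] * 100)
    fs_raw <- colMeans(fs_mat)
    ps_raw <- colMeans(ps_mat)
  } else {
    fs_raw <- colMeans(fs_mat)
    ps_raw <- colMeans(ps_mat)
    if (abs(ps_raw[t0]) < eps) {
      stop("mean power at onset below epsilon; percent change undefined",
           call. = FALSE)
    }
    fs_pct <- (fs_raw - fs_raw[t0]) / fs_raw[t0] * 100
    ps_pct <- (ps_raw - ps_raw[t0]) / ps_raw[t0] * 100
  }
  cond <- unique(epochs$labels)
  structure(
    list(
      curve = tibble::tibble(time_ms = epochs$times,
                             fs_pct = fs_pct, ps_pct = ps_pct,
                             fs_raw = fs_raw, ps_raw = ps_raw),
      band = band,
      band_label = band_label(band),
      electrode = electrode,
      condition = if (length(cond) == 1L) cond else "all",
      n_trials = n_tr
    ),
    class = "sliding_curves"
  )
}

band_label <- function(band) {
  mid <- mean(band)
  if (mid <= 8) "theta" else "alpha"
}

#' @export
print.sliding_curves <- function(x, ...) {
  cat(sprintf("<sliding_curves> %s band (%g-%g Hz) @ %s, %s, %d trials\n",
              x$band_label, x$band[1L], x$band[2L], x$electrode,
              x$condition, x$n_trials))
  invisible(x)
}

#' Percent-change FS/PS area under the curve in the fixed windows
#'
#' Signed trapezoidal AUC of the percent-change frequency- and
#' power-sliding curves over the band's stated 100-ms windows.
#'
#' @param curves A `sliding_curves` object.
#' @param windows Window table as from [auc_windows()].
#' @return One-row tibble: `band`, `condition`, `fs_auc`, `ps_auc`
#'   (percent x ms), window bounds.
#' @export
sliding_window_auc <- function(curves, windows = auc_windows()) {
  sliding_auc_impl(curves, windows, c(fs = "fs_pct", ps = "ps_pct"))
}

#' Absolute-units FS/PS area under the curve in the fixed windows
#'
#' Same windows as [sliding_window_auc()] but integrating the raw
#' trial-mean curves (Hz x ms for FS, uV^2 x ms for PS) rather than
#' percent change, probing absolute rather than relative differences.
#'
#' @inheritParams sliding_window_auc
#' @return One-row tibble: `band`, `condition`, `fs_auc`, `ps_auc`.
#' @export
sliding_absolute_auc <- function(curves, windows = auc_windows()) {
  sliding_auc_impl(curves, windows, c(fs = "fs_raw", ps = "ps_raw"))
}

sliding_auc_impl <- function(curves, windows, cols) {
  stopifnot(inherits(curves, "sliding_curves"))
  w <- windows[windows$band == curves$band_label, , drop = FALSE]
  if (nrow(w) < 2L) {
    stop("no AUC windows for band '", curves$band_label, "'", call. = FALSE)
  }
  one <- function(measure) {
    wi <- w[w$measure == measure, ]
    trapezoid_auc(curves$curve$time_ms, curves$curve[[cols[[measure]]]],
                  wi$t_start, wi$t_end)
  }
  wfs <- w[w$measure == "fs", ]
  wps <- w[w$measure == "ps", ]
  tibble::tibble(
    band = curves$band_label,
    condition = curves$condition,
    fs_auc = one("fs"), ps_auc = one("ps"),
    fs_window_start = wfs$t_start, fs_window_end = wfs$t_end,
    ps_window_start = wps$t_start, ps_window_end = wps$t_end
  )
}
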