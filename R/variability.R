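# Trial-to-trial variability (percent change of cross-trial SD relative
# to stimulus onset) and signed trapezoidal window AUC.

#' Trial-to-trial variability curve
#'
#' At every epoch timepoint the cross-trial standard deviation (sample,
#' n-1 denominator by default) is expressed as percent change relative to
#' its value at stimulus onset:
#' `TTV(t) = (sd_t - sd_0) / sd_0 * 100`. The curve is exactly 0 at onset;
#' it depends only on cross-trial dispersion, so common (trial-invariant)
#' evoked waveforms and global amplitude scalings leave it unchanged.
#'
#' @param epochs An [eeg_epochs] object; use [filter_epochs()] first to
#'   select one condition.
#' @param electrode Channel label (broadband TTV is conventionally read at
#'   Fz).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return A `ttv_curve` object: tibble `curve` (`time_ms`, `ttv_pct`) plus
#'   `electrode`, `condition`, `n_trials`.
#' @export
ttv_curve <- function(epochs, electrode, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sd_denominator <- match.arg(sd_denominator)
  m <- epoch_channel_matrix(epochs, electrode)
  n_tr <- nrow(m)
  if (n_tr < 2L) stop("need >= 2 trials for a cross-trial SD", call. = FALSE)
  mu <- colMeans(m)
  ss <- colSums(m^2) - n_tr * mu^2
  ss[ss < 0] <- 0
  denom <- if (sd_denominator == "n-1") n_tr - 1L else n_tr
  sd_t <- sqrt(ss / denom)
  sd0 <- sd_t[epochs$t0_index]
  if (sd0 <= .Machine$double.eps^0.5) {
    stop("cross-trial SD at onset is zero (identical trials); TTV undefined",
         call. = FALSE)
  }
  cond <- unique(epochs$labels)
  structure(
    list(
      curve = tibble::tibble(time_ms = epochs$times,
                             ttv_pct = (sd_t - sd0) / sd0 * 100),
      electrode = electrode,
      condition = if (length(cond) == 1L) cond else "all",
      n_trials = n_tr
    ),
    class = "ttv_curve"
  )
}

#' @export
print.ttv_curve <- function(x, ...) {
  cat(sprintf("<ttv_curve> %s @ %s, %d trials, [%g, %g] ms\n",
              x$condition, x$electrode, x$n_trials,
              min(x$curve$time_ms), max(x$curve$time_ms)))
  invisible(x)
}

#' Signed trapezoidal area under an onset-relative curve
#'
#' @param curve A `ttv_curve`, a data frame with a `time_ms` column and one
#'   value column, or a numeric vector (then `times` is required).
#' @param t_start,t_end Window in ms, within the curve's support.
#' @param times Sample times in ms when `curve` is a bare numeric vector.
#' @param absolute If `TRUE`, integrate `|curve|` instead of the signed
#'   curve (default `FALSE`; percent-change curves are signed).
#' @return Signed area in curve-units x ms.
#' @export
curve_auc <- function(curve, t_start, t_end, times = NULL, absolute = FALSE) {
  if (inherits(curve, "ttv_curve")) {
    times <- curve$curve$time_ms
    values <- curve$curve$ttv_pct
  } else if (is.data.frame(curve)) {
    if (!"time_ms" %in% names(curve)) {
      stop("data-frame curve needs a `time_ms` column", call. = FALSE)
    }
    vcol <- setdiff(names(curve), "time_ms")[1L]
    times <- curve$time_ms
    values <- curve[[vcol]]
  } else {
    if (is.null(times)) {
      stop("`times` is required for a bare numeric curve", call. = FALSE)
    }
    values <- curve
  }
  if (absolute) values <- abs(values)
  trapezoid_auc(times, values, t_start, t_end)
}
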