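# Shared numerical helpers: analytic signal, phase unwrapping, sliding
# median, FFT convolution, trapezoidal integration.

#' Analytic signal via the frequency-domain construction
#'
#' Extends a real band-limited series to its complex analytic signal whose
#' argument is the instantaneous phase and whose modulus is the
#' instantaneous amplitude (envelope).
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @examples
#' z <- analytic_signal(cos(2 * pi * 10 * seq(0, 1, by = 1 / 500)))
#' summary(Mod(z))
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector of length >= 2", call. = FALSE)
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Unwrap a phase series: remove 2*pi jumps in the first difference.
unwrap_phase <- function(phase) {
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phase[1L], phase[1L] + cumsum(d))
}

#' Sliding-window median with reflected edges
#'
#' Centered running median of window length `width`; the series is padded by
#' reflection so the output has the input's length. Values never leave the
#' input's min-max range.
#'
#' @param x Numeric vector.
#' @param width Window length in samples (>= 1). `width = 1` returns `x`.
#' @return Numeric vector, same length as `x`.
#' @export
sliding_median <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width < 1L) stop("`width` must be >= 1", call. = FALSE)
  if (width == 1L || n == 1L) return(x)
  if (width > n) width <- if (n %% 2L == 1L) n else n - 1L
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  pad_l <- x[pmin(n, seq(left + 1L, 2L, length.out = left))]
  pad_r <- x[pmax(1L, seq(n - 1L, n - right, length.out = right))]
  xp <- c(pad_l, x, pad_r)
  if (width %% 2L == 1L) {
    y <- stats::runmed(xp, k = width, endrule = "keep")
    y[(left + 1L):(left + n)]
  } else {
    vapply(seq_len(n), function(i) stats::median(xp[i:(i + width - 1L)]),
           numeric(1L))
  }
}

# Linear FIR filtering by FFT convolution ("same" alignment for a kernel of
# odd length); used by the zero-phase band-pass.
fft_convolve_same <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  m <- stats::nextn(n + k - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                       stats::fft(c(kernel, numeric(m - k))), inverse = TRUE)) / m
  half <- (k - 1L) %/% 2L
  y[(half + 1L):(half + n)]
}

# Signed trapezoidal integral of values sampled at `times` over
# [t_start, t_end]; interpolates the end points so the window need not fall
# on the sampling grid.
trapezoid_auc <- function(times, values, t_start, t_end) {
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  if (t_start < min(times) || t_end > max(times)) {
    stop("AUC window [", t_start, ", ", t_end, "] outside curve support",
         call. = FALSE)
  }
  inside <- times > t_start & times < t_end
  tt <- c(t_start, times[inside], t_end)
  vv <- c(stats::approx(times, values, xout = t_start)$y,
          values[inside],
          stats::approx(times, values, xout = t_end)$y)
  pracma::trapz(tt, vv)
}

# Batched per-trial analytic derivatives for a trials x samples matrix:
# one mvfft round trip gives every trial's analytic signal, from which the
# instantaneous-frequency (median-filtered phase derivative) and
# instantaneous-power (squared envelope) matrices are derived.
analytic_epochs <- function(m, fs, median_order) {
  n <- ncol(m)
  n_tr <- nrow(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(t(m)) * h, inverse = TRUE) / n
  phase <- Arg(z)                       # samples x trials
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  f <- fs / (2 * pi) * rbind(d[1L, , drop = FALSE], d)
  if (median_order > 0L) {
    for (j in seq_len(n_tr)) f[, j] <- sliding_median(f[, j], median_order + 1L)
  }
  list(freq = t(f), power = t(Mod(z)^2))
}

# Deterministic derived seed, kept well below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483583
  as.integer(s) + 1L
}
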