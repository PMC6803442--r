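# Independent reference implementations used as oracles, plus small
# fixture builders. These deliberately use different algorithms from the
# package code paths they check.

# Classic pointer-walk LZ76 production counter (Kaspar-Schuster index
# scheme, symbol-by-symbol; no string search).
lz76_oracle <- function(s) {
  if (is.character(s)) s <- as.integer(strsplit(s, "")[[1L]])
  s <- as.integer(s)
  n <- length(s)
  if (n == 1L) return(1L)
  i <- 0L; k <- 1L; l <- 1L; k_max <- 1L; cn <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { cn <- cn + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        cn <- cn + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cn
}

# Brute-force two-sample KS distance: sup over every observed value.
ks_d_oracle <- function(a, b) {
  xs <- c(a, b)
  max(vapply(xs, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1L)))
}

# Brute-force sliding median with reflected edges (sort-and-pick).
sliding_median_oracle <- function(x, width) {
  n <- length(x)
  left <- (width - 1L) %/% 2L
  right <- width - 1L - left
  pad_l <- if (left > 0L) x[seq(left + 1L, 2L)] else numeric(0)
  pad_r <- if (right > 0L) x[seq(n - 1L, n - right)] else numeric(0)
  xp <- c(pad_l, x, pad_r)
  vapply(seq_len(n), function(i) median(xp[i:(i + width - 1L)]), numeric(1L))
}

# Epochs whose per-trial samples come from a generating function
# f(trial, sample_index) -> value; one channel "Fz" unless labels given.
make_epochs <- function(n_trials, n_samples, t0_index, f,
                        fs = 500, labels = NULL,
                        channel_labels = "Fz") {
  data <- array(0, dim = c(n_trials, length(channel_labels), n_samples))
  for (tr in seq_len(n_trials)) {
    row <- f(tr, seq_len(n_samples))
    for (ch in seq_along(channel_labels)) data[tr, ch, ] <- row
  }
  if (is.null(labels)) labels <- rep("standard", n_trials)
  eeg_epochs(data, fs, t0_index, labels, channel_labels)
}

# A single-channel recording from a numeric vector.
make_recording <- function(x, fs = 500, label = "Fz") {
  eeg_recording(matrix(x, nrow = 1L, dimnames = list(label)), fs, label)
}
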