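# Median-threshold binarization and Lempel-Ziv (LZ76) complexity with
# length normalization; pre/post-stimulus complexity change.

#' Binarize a series at its own median
#'
#' Each sample maps to 1 when it is greater than or equal to the segment's
#' median and to 0 otherwise. The median threshold is robust to extreme
#' values in the segment.
#'
#' @param x Non-empty numeric vector.
#' @return Integer vector of 0/1 symbols, same length as `x`.
#' @export
binarize_median <- function(x) {
  if (length(x) == 0L) stop("empty segment", call. = FALSE)
  as.integer(x >= stats::median(x))
}

#' LZ76 production count of a binary sequence
#'
#' Scans the sequence left to right and counts one new "word" each time
#' the running word cannot be copied from the prior history (the history
#' including the growing word's own prefix), in the classic
#' Kaspar-Schuster production scheme; a pending final word counts once.
#'
#' @param s Vector of 0/1 symbols (integer, numeric, or a single
#'   "0101..." string).
#' @return Integer production count `c(n)`, with `1 <= c(n) <= n`.
#' @export
lz76_count <- function(s) {
  s <- as_binary_symbols(s)
  n <- length(s)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (n == 1L) return(1L)
  str <- paste(s, collapse = "")
  cn <- 0L
  i <- 1L
  while (i <= n) {
    max_k <- n - i + 1L
    # longest prefix of the remainder that can be copied from the history
    # extended by the word's own prefix (overlapping copies allowed);
    # copyability is monotone in k, so binary search it
    occurs <- function(k) {
      grepl(substr(str, i, i + k - 1L), substr(str, 1L, i + k - 2L),
            fixed = TRUE)
    }
    lo <- 0L
    hi <- max_k
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (occurs(mid)) lo <- mid else hi <- mid - 1L
    }
    cn <- cn + 1L
    if (lo == max_k) break           # pending final word, counted once
    i <- i + lo + 1L                 # copyable prefix + one novel symbol
  }
  cn
}

as_binary_symbols <- function(s) {
  if (is.character(s) && length(s) == 1L) {
    s <- as.integer(strsplit(s, "")[[1L]])
  }
  s <- as.integer(s)
  if (anyNA(s) || !all(s %in% c(0L, 1L))) {
    stop("sequence symbols must be 0/1", call. = FALSE)
  }
  s
}

#' Length-normalized Lempel-Ziv complexity
#'
#' `C(n) = c(n) / (n / log2(n))`, which is approximately 1 for a fair-coin
#' random binary sequence and tends to 0 for a constant one as n grows.
#'
#' @param s Vector of 0/1 symbols (or a "0101..." string) of length >= 2.
#' @return Normalized complexity `C(n)` (unitless, > 0).
#' @export
normalized_lzc <- function(s) {
  s <- as_binary_symbols(s)
  n <- length(s)
  if (n < 2L) stop("need length >= 2 to normalize (log2 n > 0)", call. = FALSE)
  lz76_count(s) / (n / log2(n))
}

#' Pre- versus post-stimulus Lempel-Ziv complexity
#'
#' For each trial, the `window_ms` of signal before onset (`[-w, 0)`) and
#' after onset (`[0, +w)`, onset sample included) are binarized at their
#' own medians and their normalized LZ76 complexities computed; per-trial
#' values are averaged within each condition. `diff = post - pre`, so a
#' post-stimulus regularity increase shows as a negative difference.
#'
#' @param epochs An [eeg_epochs] object (any mix of conditions).
#' @param electrode Channel label.
#' @param window_ms One-sided window length in ms (default 300).
#' @param per_trial If `TRUE` (default) LZC is computed per trial and then
#'   averaged; if `FALSE` it is computed once on the trial-averaged signal.
#' @return Tibble with one row per condition: `condition`, `pre`, `post`,
#'   `diff`, `n_trials`.
#' @export
lzc_prepost <- function(epochs, electrode, window_ms = 300,
                        per_trial = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  w <- round(window_ms * epochs$fs / 1000)
  n_samp <- dim(epochs$data)[3L]
  t0 <- epochs$t0_index
  if (t0 - w < 1L || t0 + w - 1L > n_samp) {
    stop("window of ", window_ms, " ms does not fit the epoch on both sides",
         call. = FALSE)
  }
  m <- epoch_channel_matrix(epochs, electrode)
  pre_idx <- (t0 - w):(t0 - 1L)
  post_idx <- t0:(t0 + w - 1L)
  lzc_of <- function(seg) normalized_lzc(binarize_median(seg))
  conds <- unique(epochs$labels)
  purrr::map_dfr(conds, function(cond) {
    rows <- which(epochs$labels == cond)
    if (per_trial) {
      pre <- mean(vapply(rows, function(i) lzc_of(m[i, pre_idx]), numeric(1L)))
      post <- mean(vapply(rows, function(i) lzc_of(m[i, post_idx]), numeric(1L)))
    } else {
      avg <- colMeans(m[rows, , drop = FALSE])
      pre <- lzc_of(avg[pre_idx])
      post <- lzc_of(avg[post_idx])
    }
    tibble::tibble(condition = cond, pre = pre, post = post,
                   diff = post - pre, n_trials = length(rows))
  })
}
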