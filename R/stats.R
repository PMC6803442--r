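# Nonparametric group comparison (two-sample Kolmogorov-Smirnov), rank
# correlation (Spearman), and Benjamini-Hochberg FDR control, all
# returned as tidy one-row tibbles that stack into results tables.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the full empirical distributions of two samples via
#' `D = sup_x |ECDF_a(x) - ECDF_b(x)|`, with a two-sided p-value (exact
#' when `n1 * n2 <= 10000` and no ties are present, asymptotic otherwise).
#' Distribution-level comparison is robust to outlying subjects and
#' usable at small group sizes.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param description Label for the comparison (carried in the result row).
#' @param family Multiple-testing family label (used by
#'   [adjust_families()]).
#' @return One-row tibble: `family`, `description`, `method`, `statistic`
#'   (D), `n1`, `n2`, `p_raw`, `p_adj` (`NA` until adjusted).
#' @export
ks_two_sample <- function(a, b, description = "ks", family = "default") {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs >= 2 observations", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  exact <- length(a) * length(b) <= 10000
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  tibble::tibble(
    family = family, description = description, method = "ks",
    statistic = unname(res$statistic),
    n1 = length(a), n2 = length(b),
    p_raw = min(1, res$p.value), p_adj = NA_real_
  )
}

#' Spearman rank correlation
#'
#' Two-tailed Spearman correlation: Pearson correlation of average-tie-
#' corrected ranks, p-value from the t approximation.
#'
#' @param x,y Paired numeric samples of equal length >= 3.
#' @param description,family As in [ks_two_sample()].
#' @return One-row tibble with `statistic` = rho; `n1 = n2 =` sample size.
#' @export
spearman_corr <- function(x, y, description = "spearman",
                          family = "default") {
  if (length(x) != length(y)) stop("`x`, `y` must be paired", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided")
  )
  tibble::tibble(
    family = family, description = description, method = "spearman",
    statistic = unname(res$estimate),
    n1 = n, n2 = n,
    p_raw = min(1, res$p.value), p_adj = NA_real_
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply `p_(i)` by `m / i`,
#' enforce monotone non-decrease from the largest down, cap at 1, and
#' return in the original order. Controls the expected false-discovery
#' proportion at the chosen level.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Adjust a stacked results table per family
#'
#' Applies [bh_adjust()] to `p_raw` within each `family`, filling `p_adj`.
#'
#' @param results Tibble of stacked [ks_two_sample()] /
#'   [spearman_corr()] rows.
#' @param mode `"per_family"` (default) corrects each family on its own;
#'   `"global"` pools all rows into one family.
#' @return The table with `p_adj` filled.
#' @export
adjust_families <- function(results, mode = c("per_family", "global")) {
  mode <- match.arg(mode)
  if (nrow(results) == 0L) return(results)
  if (mode == "global") {
    results$p_adj <- bh_adjust(results$p_raw)
    results
  } else {
    results |>
      dplyr::group_by(.data$family) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  }
}
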