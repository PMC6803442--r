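# broom-style accessors for the fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a result bundle
#'
#' Stacks the group tests and correlations into one tibble with a
#' `result_type` column.
#'
#' @param x An `eeg_result_bundle`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eeg_result_bundle <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$group_tests, result_type = "group_test"),
    dplyr::mutate(x$correlations, result_type = "correlation")
  )
}

#' One-row summary of a result bundle
#'
#' @param x An `eeg_result_bundle`.
#' @param alpha Significance level on adjusted p-values.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.eeg_result_bundle <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$rest_summaries$subject)),
    n_task_subjects = length(unique(x$task_measures$subject)),
    n_group_tests = nrow(x$group_tests),
    n_group_sig = sum(x$group_tests$p_adj < alpha, na.rm = TRUE),
    n_correlations = nrow(x$correlations),
    n_corr_sig = sum(x$correlations$p_adj < alpha, na.rm = TRUE)
  )
}

#' @export
tidy.ttv_curve <- function(x, ...) {
  dplyr::mutate(x$curve, electrode = x$electrode, condition = x$condition,
                n_trials = x$n_trials)
}

#' @export
tidy.sliding_curves <- function(x, ...) {
  dplyr::mutate(x$curve, band = x$band_label, electrode = x$electrode,
                condition = x$condition, n_trials = x$n_trials)
}
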