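# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trial-to-trial variability curve
#'
#' @param object A `ttv_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttv_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time_ms, y = .data$ttv_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from stimulus onset (ms)",
      y = "TTV (% change of cross-trial SD)",
      title = sprintf("Trial-to-trial variability: %s at %s (%d trials)",
                      object$condition, object$electrode, object$n_trials)
    ) +
    ggplot2::theme_minimal()
}

#' Plot frequency- and power-sliding curves
#'
#' Percent-change FS and PS around onset, with the band's fixed AUC
#' windows shaded.
#'
#' @param object A `sliding_curves` object.
#' @param windows AUC window table ([auc_windows()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sliding_curves <- function(object, windows = auc_windows(), ...) {
  long <- tidyr::pivot_longer(
    object$curve[, c("time_ms", "fs_pct", "ps_pct")],
    cols = c("fs_pct", "ps_pct"),
    names_to = "measure", values_to = "pct"
  )
  long$measure <- ifelse(long$measure == "fs_pct",
                         "Frequency sliding", "Power sliding")
  w <- windows[windows$band == object$band_label, ]
  w$measure <- ifelse(w$measure == "fs", "Frequency sliding",
                      "Power sliding")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$pct)) +
    ggplot2::geom_rect(
      data = w,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1L, scales = "free_y") +
    ggplot2::labs(
      x = "Time from stimulus onset (ms)",
      y = "% change from onset",
      title = sprintf("%s band (%g-%g Hz), %s at %s",
                      object$band_label, object$band[1L], object$band[2L],
                      object$condition, object$electrode)
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of group-comparison results
#'
#' KS D per comparison, coloured by FDR-adjusted significance.
#'
#' @param bundle An `eeg_result_bundle`.
#' @param alpha Significance level on the adjusted p-values.
#' @return A ggplot.
#' @export
plot_group_tests <- function(bundle, alpha = 0.05) {
  stopifnot(inherits(bundle, "eeg_result_bundle"))
  gt <- bundle$group_tests
  gt$significant <- gt$p_adj < alpha
  ggplot2::ggplot(gt, ggplot2::aes(x = .data$statistic,
                                   y = .data$description,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = sprintf("adj. p < %g", alpha)
    ) +
    ggplot2::labs(x = "Kolmogorov-Smirnov D (MDD vs CON)", y = NULL) +
    ggplot2::theme_minimal()
}
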