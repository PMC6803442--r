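# Cohort-level helpers for the end-to-end recovery checks: scaled-down
# study conditions (fewer trials / shorter rest than the full session)
# chosen once as the suite's Monte-Carlo problem size.

# Per-subject rest summaries and deviant/novel task measures, without the
# parts of the full pipeline the recovery checks do not read.
cohort_recovery_measures <- function(cohort, conditions = "deviant",
                                     with_rest = TRUE) {
  rows <- lapply(cohort$subjects, function(sub) {
    out <- list(subject = sub$id, group = sub$group)
    if (with_rest) {
      th <- resting_summary(sub$rest, "Fz", c(4, 8))
      al <- resting_summary(sub$rest, "Pz", c(8, 13))
      out$theta_pf <- th$mean_pf
      out$theta_power <- th$mean_power
      out$theta_cv <- th$cv
      out$alpha_pf <- al$mean_pf
      out$alpha_power <- al$mean_power
      out$alpha_cv <- al$cv
    }
    bb <- fir_bandpass(
      eeg_recording(sub$task$data["Fz", , drop = FALSE], sub$task$fs, "Fz"),
      1, 40)
    ep <- suppressWarnings(epoch_recording(bb, sub$events, -500, 800))
    for (cond in conditions) {
      sel <- filter_epochs(ep, cond)
      out[[paste0("ttv_", cond)]] <-
        curve_auc(ttv_curve(sel, "Fz"), 0, 500)
      out[[paste0("lzc_", cond)]] <- lzc_prepost(sel, "Fz", 300)$diff
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

group_mean_diff <- function(df, col) {
  mean(df[[col]][df$group == "MDD"]) - mean(df[[col]][df$group == "CON"])
}

# Two templates identical except for the deviant variability quench;
# background-noise dominated so the quench maps almost directly onto TTV.
quench_only_templates <- function(q_a = -0.4, q_b = -0.1) {
  base <- subject_config(
    theta = oscillator_spec("theta", 5.7, 0.4, amplitude = 1.5),
    alpha = oscillator_spec("alpha", 10.4, 0.3, amplitude = 1.5),
    noise_amplitude = 8,
    quench = c(standard = -0.2, deviant = q_a, novel = -0.2)
  )
  strong <- base
  weak <- base
  weak$quench[["deviant"]] <- q_b
  list(strong = strong, weak = weak)
}
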