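# The two-group rest + oddball simulator.

test_that("configuration invariants are enforced", {
  expect_error(oscillator_spec("theta", 10, 0.3), "inside the theta band")
  expect_error(oscillator_spec("alpha", 10, -1), "pf_wander_sd")
  expect_error(subject_config(quench = c(standard = -1.2, deviant = 0,
                                         novel = 0)), "> -1")
  expect_error(cohort_config(n_per_group = 1L), ">= 2")
  expect_error(cohort_config(proportions = c(standard = 0.7, deviant = 0.2,
                                             novel = 0.2)), "sum to 1")
  expect_error(cohort_config(n_trials = 10L,
                             proportions = c(standard = 0.85, deviant = 0.05,
                                             novel = 0.10)), "integer")
  expect_error(simulate_resting(template_con(), -5, 500, 1), "positive")
})

test_that("rest generation is seeded and sized as configured", {
  sub <- template_con()
  r1 <- simulate_resting(sub, 180, 500, 10)
  expect_identical(ncol(r1$data), 90000L)   # 3 min at 500 Hz
  expect_true(all(c("Fz", "Pz") %in% r1$channel_labels))
  r2 <- simulate_resting(sub, 180, 500, 10)
  r3 <- simulate_resting(sub, 180, 500, 11)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))
})

test_that("the event stream honors the 80/10/10 oddball proportions", {
  cc <- cohort_config(n_per_group = 2, seed = 3)       # default 800 trials
  tk <- simulate_task(template_con(), cc, 21)
  counts <- table(tk$events$label)
  expect_identical(as.integer(counts[c("standard", "deviant", "novel")]),
                   c(640L, 80L, 80L))
  expect_true(all(diff(tk$events$onset_sample) > 0))
  # reaction times exist for deviants only
  expect_identical(sum(!is.na(tk$events$rt_ms)), 80L)
  expect_true(all(is.na(tk$events$rt_ms[tk$events$label != "deviant"])))
  tk2 <- simulate_task(template_con(), cc, 21)
  expect_identical(tk$recording$data, tk2$recording$data)
  expect_identical(tk$events, tk2$events)
})

test_that("configured mean peak frequency is recovered within 0.2 Hz", {
  sub <- subject_config(alpha = oscillator_spec("alpha", 10, 0.3,
                                                amplitude = 6))
  rec <- simulate_resting(sub, 170, 500, 7)
  est <- resting_summary(rec, "Pz", c(7, 13))
  expect_lt(abs(est$mean_pf - 10), 0.2)
  th <- resting_summary(rec, "Fz", c(4, 8))
  expect_lt(abs(th$mean_pf - 5.7), 0.25)
})

test_that("deviant TTV response increases with the quench magnitude", {
  cc <- cohort_config(n_per_group = 2, rest_duration = 10, n_trials = 300,
                      proportions = c(standard = 1 / 3, deviant = 1 / 3,
                                      novel = 1 / 3), seed = 5)
  auc_for <- function(q) {
    sub <- template_con()
    sub$quench[] <- c(0.2, q, 0.2)
    tk <- simulate_task(sub, cc, 77)
    bb <- fir_bandpass(
      eeg_recording(tk$recording$data["Fz", , drop = FALSE], 500, "Fz"),
      1, 40)
    ep <- epoch_recording(bb, tk$events, -500, 800)
    curve_auc(ttv_curve(filter_epochs(ep, "deviant"), "Fz"), 0, 500)
  }
  aucs <- vapply(c(0, 0.2, 0.45), auc_for, numeric(1L))
  expect_true(all(diff(abs(aucs)) > 0))
  # no modulation -> mean TTV near zero up to sampling error
  tc0 <- abs(aucs[1L]) / 500                       # mean % over the window
  expect_lt(tc0, 10)
})

test_that("between-subject jitter varies parameters around the template", {
  cfgs <- lapply(1:12, function(i) {
    eegdyn:::jitter_subject(template_con(), 100 + i)
  })
  pf <- vapply(cfgs, function(s) s$theta$mean_pf, numeric(1L))
  expect_gt(sd(pf), 0)
  expect_lt(abs(mean(pf) - 5.7), 0.35)
  expect_lt(sd(pf) / mean(pf), 0.12)               # ~5% relative jitter
})

test_that("cohorts are balanced and deterministic", {
  cc <- cohort_config(n_per_group = 3, rest_duration = 5, n_trials = 20,
                      seed = 13)
  coh <- simulate_cohort(cc)
  expect_length(coh$subjects, 6L)
  groups <- vapply(coh$subjects, `[[`, character(1L), "group")
  expect_identical(as.integer(table(groups)), c(3L, 3L))
  coh2 <- simulate_cohort(cc)
  expect_identical(coh$subjects[[5L]]$rest$data, coh2$subjects[[5L]]$rest$data)
  expect_identical(coh$subjects[[2L]]$task$data, coh2$subjects[[2L]]$task$data)
})

test_that("stronger variability coupling speeds deviant reaction times", {
  # across subjects, larger |quench| must mean faster mean RT and larger
  # TTV AUC: negative Spearman between deviant TTV AUC and mean RT
  tpl <- subject_config(
    theta = oscillator_spec("theta", 5.7, 0.4, amplitude = 1.5),
    alpha = oscillator_spec("alpha", 10.4, 0.3, amplitude = 1.5),
    noise_amplitude = 8,
    quench = c(standard = 0.2, deviant = 0.45, novel = 0.2)
  )
  cc <- cohort_config(n_per_group = 2, rest_duration = 5, n_trials = 150,
                      proportions = c(standard = 1 / 3, deviant = 1 / 3,
                                      novel = 1 / 3), seed = 2)
  stats <- vapply(1:30, function(i) {
    sub <- eegdyn:::jitter_subject(tpl, 5000 + i, rel_sd = 0.35)
    tk <- simulate_task(sub, cc, 6000 + i)
    bb <- fir_bandpass(
      eeg_recording(tk$recording$data["Fz", , drop = FALSE], 500, "Fz"),
      1, 40)
    ep <- epoch_recording(bb, tk$events, -500, 800)
    c(auc = curve_auc(ttv_curve(filter_epochs(ep, "deviant"), "Fz"), 0, 500),
      rt = mean(tk$reaction_times))
  }, numeric(2L))
  rho <- spearman_corr(stats["auc", ], stats["rt", ])$statistic
  expect_lt(rho, 0)
})
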