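# Frequency / power sliding and the fixed AUC windows.

fs <- 500

# Epochs with a controlled instantaneous-frequency and amplitude profile:
# phase-continuous oscillation, per-trial random phase offset.
profile_epochs <- function(n_trials, freq_profile, amp_profile = NULL,
                           t0 = 251L, n_s = 650L) {
  if (is.null(amp_profile)) amp_profile <- rep(1, n_s)
  set.seed(61)
  make_epochs(n_trials, n_s, t0, function(tr, idx) {
    phase <- 2 * pi * cumsum(freq_profile) / fs + tr
    amp_profile * cos(phase)
  })
}

# linear transition between two levels over [from_ms, to_ms] post-onset
level_profile <- function(before, after, from_ms, to_ms, t0 = 251L,
                          n_s = 650L) {
  t_ms <- (seq_len(n_s) - t0) * 1000 / fs
  w <- pmin(1, pmax(0, (t_ms - from_ms) / (to_ms - from_ms)))
  before + (after - before) * w
}

test_that("constant-frequency trials give a flat percent-change FS", {
  ep <- profile_epochs(5, rep(10, 650))
  sc <- sliding_curves(ep, c(7, 13), "Fz")
  expect_identical(sc$curve$fs_pct[251L], 0)
  expect_identical(sc$curve$ps_pct[251L], 0)
  mid <- abs(sc$curve$time_ms) <= 500
  expect_lt(max(abs(sc$curve$fs_pct[mid])), 0.5)
  auc <- sliding_window_auc(sc)
  expect_lt(abs(auc$fs_auc), 30)
  # absolute FS AUC: 10 Hz over the 100 ms window
  abs_auc <- sliding_absolute_auc(sc)
  expect_equal(abs_auc$fs_auc, 1000, tolerance = 0.01)
})

test_that("a +10% frequency step lands in the alpha FS window", {
  freq <- level_profile(10, 11, 50, 150)
  sc <- sliding_curves(profile_epochs(5, freq), c(7, 13), "Fz")
  auc <- sliding_window_auc(sc)
  expect_identical(auc$fs_window_start, 376)
  expect_lt(abs(auc$fs_auc - 1000) / 1000, 0.10)
})

test_that("post-onset amplitude doubling shows as +300% power sliding", {
  amp <- level_profile(1, 2, 30, 130)
  sc <- sliding_curves(profile_epochs(5, rep(10, 650), amp), c(7, 13), "Fz")
  auc <- sliding_window_auc(sc)
  # power x4 -> +300%; alpha PS window 150-250 ms
  expect_lt(abs(auc$ps_auc - 30000) / 30000, 0.10)
  # the corresponding theta-band windows are distinct
  expect_identical(auc$ps_window_start, 150)
})

test_that("percent-change curves are amplitude-invariant, raw PS is not", {
  freq <- level_profile(10, 10.5, 50, 150)
  ep1 <- profile_epochs(4, freq)
  ep2 <- eeg_epochs(ep1$data * 3, ep1$fs, ep1$t0_index, ep1$labels,
                    ep1$channel_labels)
  s1 <- sliding_curves(ep1, c(7, 13), "Fz")
  s2 <- sliding_curves(ep2, c(7, 13), "Fz")
  expect_equal(s2$curve$fs_pct, s1$curve$fs_pct, tolerance = 1e-8)
  expect_equal(s2$curve$ps_pct, s1$curve$ps_pct, tolerance = 1e-8)
  expect_equal(s2$curve$ps_raw, 9 * s1$curve$ps_raw, tolerance = 1e-8)
  expect_equal(s2$curve$fs_raw, s1$curve$fs_raw, tolerance = 1e-8)
  # signs of percent-change and absolute AUC agree for positive baselines
  a_pct <- sliding_window_auc(s1)
  a_abs <- sliding_absolute_auc(s1)
  expect_identical(sign(a_pct$fs_auc), sign(a_abs$fs_auc))
})

test_that("theta measures use the theta windows", {
  freq <- level_profile(6, 6.6, 50, 150)
  sc <- sliding_curves(profile_epochs(4, freq), c(4, 8), "Fz")
  expect_identical(sc$band_label, "theta")
  auc <- sliding_window_auc(sc)
  expect_identical(c(auc$fs_window_start, auc$fs_window_end), c(400, 500))
  expect_identical(c(auc$ps_window_start, auc$ps_window_end), c(166, 266))
  expect_lt(abs(auc$fs_auc - 1000) / 1000, 0.10)
})

test_that("per-trial percent change is available and distinct", {
  set.seed(90)
  # trials differ in envelope shape, so mean-then-percent and
  # percent-then-mean genuinely disagree
  ep <- make_epochs(6, 650, 251L, function(tr, idx) {
    cos(2 * pi * 10 * idx / fs + tr) * (1 + 0.3 * sin(idx / 40 + 2 * tr))
  })
  mean_first <- sliding_curves(ep, c(7, 13), "Fz")
  per_trial <- sliding_curves(ep, c(7, 13), "Fz", per_trial_percent = TRUE)
  expect_identical(per_trial$curve$ps_pct[251L], 0)
  expect_false(isTRUE(all.equal(mean_first$curve$ps_pct,
                                per_trial$curve$ps_pct)))
})

test_that("degenerate onset power is rejected", {
  ep <- make_epochs(3, 650, 251L, function(tr, idx) numeric(650))
  expect_error(sliding_curves(ep, c(7, 13), "Fz"), "onset")
})
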