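# Zero-phase FIR band-pass, epoching, and trial subsampling.

fs <- 500

test_that("band-pass passes in-band and rejects out-of-band tones", {
  t <- seq(1 / fs, 8, by = 1 / fs)
  n <- length(t)
  rec <- eeg_recording(rbind(Fz = cos(2 * pi * 10 * t),
                             Pz = cos(2 * pi * 20 * t)),
                       fs, c("Fz", "Pz"))
  out <- fir_bandpass(rec, 7, 13, transition_fraction = 0.15)
  trim <- 2200L
  rms <- function(v) sqrt(mean(v^2))
  mid <- trim:(n - trim)
  expect_lt(abs(rms(out$data["Fz", mid]) / rms(rec$data["Fz", mid]) - 1),
            0.05)
  atten_db <- 20 * log10(rms(out$data["Pz", mid]) / rms(rec$data["Pz", mid]))
  expect_lt(atten_db, -20)
  expect_error(fir_bandpass(rec, 10, 300), "invalid band")
})

test_that("filtering is linear and maps zero to zero", {
  set.seed(8)
  x <- rnorm(4000)
  rec <- make_recording(x)
  out1 <- fir_bandpass(rec, 4, 8)
  out3 <- fir_bandpass(make_recording(3 * x), 4, 8)
  expect_equal(out3$data, 3 * out1$data, tolerance = 1e-10)
  zero <- fir_bandpass(make_recording(numeric(4000)), 4, 8)
  expect_equal(max(abs(zero$data)), 0)
})

test_that("epoching follows the half-open onset convention", {
  rec <- make_recording(as.numeric(1:5000))
  events <- tibble::tibble(onset_sample = c(1000L, 2000L, 3000L),
                           label = c("standard", "deviant", "novel"))
  ep <- epoch_recording(rec, events, tmin = -300, tmax = 600)
  expect_identical(dim(ep$data)[3L], 450L)   # [-300, 600) ms at 500 Hz
  expect_identical(ep$t0_index, 151L)        # 150 pre-onset samples
  expect_identical(ep$times[ep$t0_index], 0)
  expect_identical(ep$labels, c("standard", "deviant", "novel"))
  # the onset sample itself belongs to the post-stimulus side
  expect_identical(ep$data[1L, 1L, 151L], 1000)
  # no baseline correction: raw samples preserved exactly
  expect_identical(ep$data[2L, 1L, ], as.numeric(1850:2299))
})

test_that("events too close to an edge are dropped, all-dropped errors", {
  rec <- make_recording(rnorm(1000))
  events <- tibble::tibble(onset_sample = c(10L, 500L),
                           label = c("standard", "deviant"))
  expect_warning(ep <- epoch_recording(rec, events, -300, 600), "dropped")
  expect_identical(dim(ep$data)[1L], 1L)
  expect_identical(ep$labels, "deviant")
  bad <- tibble::tibble(onset_sample = 5L, label = "standard")
  expect_warning(
    expect_error(epoch_recording(rec, bad, -300, 600), "outside"),
    "dropped")
})

test_that("concatenating contiguous epochs reconstructs the recording", {
  x <- rnorm(2000)
  rec <- make_recording(x)
  # back-to-back 100-sample epochs: [-40, 60) ms at 500 Hz = 50 samples
  onsets <- seq(101L, 1601L, by = 50L)
  events <- tibble::tibble(onset_sample = onsets,
                           label = rep("standard", length(onsets)))
  ep <- epoch_recording(rec, events, tmin = -50, tmax = 50)
  covered <- as.vector(t(ep$data[, 1L, ]))
  expect_identical(covered, x[(onsets[1L] - 25L):(onsets[length(onsets)] + 24L)])
})

test_that("subsampling is seeded, order-preserving, and bit-exact", {
  set.seed(2)
  ep <- make_epochs(640, 100, 50L, function(tr, idx) rnorm(100) + tr)
  s1 <- subsample_trials(ep, "standard", 80, seed = 7)
  s2 <- subsample_trials(ep, "standard", 80, seed = 7)
  s3 <- subsample_trials(ep, "standard", 80, seed = 8)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
  expect_identical(dim(s1$data)[1L], 80L)
  # original trial order retained: trial means strictly increasing
  means <- apply(s1$data[, 1L, ], 1L, mean)
  expect_true(all(diff(means) > 0))
  # identity selection when n equals availability
  all80 <- make_epochs(80, 50, 25L, function(tr, idx) rnorm(50))
  expect_identical(subsample_trials(all80, "standard", 80, 1)$data,
                   all80$data)
  expect_error(subsample_trials(all80, "standard", 81, 1),
               "only 80 with label")
})
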