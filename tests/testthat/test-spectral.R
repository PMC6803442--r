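# Instantaneous frequency / power and the resting PF / CV / power summary.

fs <- 500

test_that("pure tones are recovered by the analytic phase derivative", {
  t <- seq(1 / fs, 4, by = 1 / fs)
  for (f0 in c(8, 10, 12)) {
    f <- instantaneous_frequency(cos(2 * pi * f0 * t), fs)
    mid <- 200:1800
    expect_lt(abs(mean(f[mid]) - f0), 0.05)
    expect_lt(sd(f[mid]), 0.05)
  }
  expect_error(instantaneous_frequency(numeric(100) * 0, fs), "all-zero")
})

test_that("a linear chirp's slope is recovered within 5%", {
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- cos(2 * pi * (8 * t + 0.2 * t^2))      # 8 -> 12 Hz, 0.4 Hz/s
  f <- instantaneous_frequency(x, fs)
  keep <- 500:4500
  slope <- unname(coef(lm(f[keep] ~ t[keep]))[2L])
  expect_lt(abs(slope - 0.4) / 0.4, 0.05)
})

test_that("instantaneous frequency is amplitude-invariant", {
  t <- seq(1 / fs, 2, by = 1 / fs)
  x <- cos(2 * pi * 9 * t) + 0.2 * cos(2 * pi * 11 * t)
  expect_equal(instantaneous_frequency(5 * x, fs),
               instantaneous_frequency(x, fs), tolerance = 1e-9)
})

test_that("instantaneous power is the squared envelope", {
  t <- seq(1 / fs, 2, by = 1 / fs)
  mid <- 200:800
  p1 <- instantaneous_power(cos(2 * pi * 10 * t))
  expect_equal(mean(p1[mid]), 1, tolerance = 1e-3)
  p2 <- instantaneous_power(2 * cos(2 * pi * 10 * t))
  expect_equal(mean(p2[mid]), 4, tolerance = 4e-3)
  expect_equal(instantaneous_power(numeric(100)), numeric(100))
})

test_that("sliding median matches brute force and preserves range", {
  set.seed(3)
  for (w in c(3, 5, 11, 4)) {
    x <- rnorm(60)
    expect_equal(sliding_median(x, w), sliding_median_oracle(x, w))
    y <- sliding_median(x, w)
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  }
  xc <- rep(2.5, 30)
  expect_equal(sliding_median(xc, 11), xc)   # idempotent on constants
})

test_that("pf_stats implements sd/mean", {
  expect_equal(pf_stats(rep(10, 100))$cv, 0)
  s <- pf_stats(c(9, 10, 11))
  expect_equal(s$mean_pf, 10)
  expect_equal(s$cv, 0.1)               # sample SD 1.0 over mean 10
})

test_that("resting_summary is phase-true under amplitude scaling", {
  t <- seq(1 / fs, 30, by = 1 / fs)
  set.seed(12)
  x <- cos(2 * pi * 10 * t) + 0.3 * rnorm(length(t))
  r1 <- resting_summary(make_recording(x), "Fz", c(7, 13))
  r2 <- resting_summary(make_recording(2 * x), "Fz", c(7, 13))
  expect_equal(r2$mean_power / r1$mean_power, 4, tolerance = 1e-9)
  expect_equal(r2$mean_pf, r1$mean_pf, tolerance = 1e-9)
  expect_equal(r2$cv, r1$cv, tolerance = 1e-9)
  expect_lt(abs(r1$mean_pf - 10), 0.1)
  expect_error(resting_summary(make_recording(x), "Cz", c(7, 13)),
               "channel not found")
})

test_that("recordings longer than max_samples are truncated first", {
  t <- seq(1 / fs, 40, by = 1 / fs)
  x <- cos(2 * pi * 10 * t)
  r_cut <- resting_summary(make_recording(x), "Fz", c(7, 13),
                           max_samples = 10000L)
  r_manual <- resting_summary(make_recording(x[1:10000]), "Fz", c(7, 13))
  expect_equal(r_cut, r_manual)
})
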