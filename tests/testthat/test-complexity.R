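# Median binarization and LZ76 complexity.

test_that("binarize_median applies the >= median rule", {
  expect_identical(binarize_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_identical(binarize_median(c(3, 1, 2)), c(1L, 0L, 1L))
  # every sample equals the median, and ties go to 1
  expect_identical(binarize_median(rep(2.5, 6)), rep(1L, 6))
  expect_error(binarize_median(numeric(0)), "empty")
})

test_that("lz76_count matches hand-parsed fixtures", {
  expect_identical(lz76_count("0001101001000101"), 6L)   # 0|001|10|100|1000|101
  expect_identical(lz76_count("00000000"), 2L)           # 0|0000000
  expect_identical(lz76_count("01"), 2L)                 # 0|1
  expect_identical(lz76_count("0"), 1L)
  expect_error(lz76_count("021"), "0/1")
})

test_that("lz76_count agrees with the pointer-walk parser on random input", {
  set.seed(421)
  for (r in 1:200) {
    s <- sample(0:1, sample(2:64, 1L), replace = TRUE)
    expect_identical(lz76_count(s), lz76_oracle(s))
  }
})

test_that("lz76_count is invariant under global bit flip and bounded", {
  set.seed(7)
  for (r in 1:50) {
    s <- sample(0:1, sample(2:100, 1L), replace = TRUE)
    cn <- lz76_count(s)
    expect_identical(cn, lz76_count(1L - s))
    expect_gte(cn, 1L)
    expect_lte(cn, length(s))
  }
})

test_that("normalized_lzc follows the n / log2(n) normalization", {
  expect_equal(normalized_lzc("0001101001000101"), 6 / (16 / 4))  # = 1.5
  expect_equal(normalized_lzc(rep(0L, 1024)), 2 / (1024 / 10))    # ~ 0.0195
  expect_error(normalized_lzc(c(0L)), "length >= 2")
  expect_gt(normalized_lzc(c(0L, 1L)), 0)
})

test_that("shuffling a periodic sequence does not lower its complexity", {
  s <- rep(c(0L, 1L), 50)
  base <- normalized_lzc(s)
  set.seed(99)
  shuffled <- replicate(100, normalized_lzc(sample(s)))
  expect_gte(median(shuffled), base)
})

test_that("lzc_prepost windows, symmetry and regularity direction", {
  # 300 ms at 500 Hz -> 150 samples per window
  n_pre <- 250L
  set.seed(5)
  noise <- matrix(rnorm(20 * 500), nrow = 20)
  ep <- make_epochs(20, 500, n_pre + 1L, function(tr, idx) noise[tr, idx])
  res <- lzc_prepost(ep, "Fz", window_ms = 300)
  expect_identical(nrow(res), 1L)
  expect_equal(res$diff, res$post - res$pre)

  # mirrored epochs: post window bit-identical to pre window -> diff = 0
  mirror <- make_epochs(10, 400, 201L, function(tr, idx) {
    w <- sin(idx[1:150] / 7 + tr)
    c(numeric(50), w, w, numeric(50))
  })
  expect_equal(lzc_prepost(mirror, "Fz", window_ms = 300)$diff, 0)

  # constant post window -> minimal complexity, diff < 0 for structured pre
  const_post <- make_epochs(10, 400, 201L, function(tr, idx) {
    c(rnorm(200), rep(0, 200))
  })
  res2 <- lzc_prepost(const_post, "Fz", window_ms = 300)
  all_ones <- normalized_lzc(rep(1L, 150))
  expect_equal(res2$post, all_ones)
  expect_lt(res2$diff, 0)

  expect_error(lzc_prepost(ep, "Fz", window_ms = 2000), "fit the epoch")
})

test_that("per-trial and trial-average LZC orders are both available", {
  set.seed(11)
  ep <- make_epochs(8, 400, 201L, function(tr, idx) rnorm(400))
  per_trial <- lzc_prepost(ep, "Fz", 300, per_trial = TRUE)
  averaged <- lzc_prepost(ep, "Fz", 300, per_trial = FALSE)
  expect_false(isTRUE(all.equal(per_trial$pre, averaged$pre)))
  expect_identical(per_trial$n_trials, 8L)
})
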