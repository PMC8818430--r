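test_that("extrema of a sampled sine land on the analytic positions", {
  x <- tone(1, fs = 1000, dur = 2)           # maxima at t = 0.25, 1.25
  ex <- find_extrema(x)
  expect_equal(length(ex$max_idx), 2)
  expect_equal(length(ex$min_idx), 2)
  expect_true(all(abs(ex$max_idx - c(251, 1251)) <= 1))
  expect_true(all(abs(ex$min_idx - c(751, 1751)) <= 1))
})

test_that("monotone ramps have no interior extrema and plateaus count once", {
  ex <- find_extrema(seq(0, 1, length.out = 100))
  expect_length(ex$max_idx, 0)
  expect_length(ex$min_idx, 0)

  ex2 <- find_extrema(c(0, 1, 1, 0))
  expect_length(ex2$max_idx, 1)
  expect_equal(ex2$max_val, 1)
  expect_true(ex2$max_idx %in% c(2, 3))      # plateau midpoint
})

test_that("spline envelopes interpolate extrema and track a sine's peaks", {
  env <- spline_envelope(c(10, 50, 90), rep(1, 3), 100)
  expect_true(all(abs(env - 1) < 1e-9))

  env2 <- spline_envelope(c(10, 90), c(1, 2), 100)
  expect_true(all(is.finite(env2)))

  x <- tone(5, fs = 1000, dur = 2)
  ex <- find_extrema(x)
  env3 <- spline_envelope(ex$max_idx, ex$max_val, length(x))
  cw <- viemdar:::central_window(length(x), 0.8)
  expect_true(all(abs(env3[cw] - 1) < 0.02))
  expect_true(all(abs(env3[ex$max_idx] - ex$max_val) < 1e-9))
})

test_that("one sifting step removes the envelope mean and is exactly additive", {
  h <- tone(10, fs = 1000, dur = 2)
  st <- sift_once(h)
  cw <- viemdar:::central_window(length(h), 0.8)
  expect_lt(max(abs(st$m[cw])), 0.05 * max(abs(h)))
  expect_identical(st$h_next + st$m, h)

  h2 <- h + 5
  st2 <- sift_once(h2)
  expect_lt(abs(mean(st2$m[cw]) - 5), 0.1)
})

test_that("IMF admissibility separates sinusoids from offset and mixtures", {
  expect_true(as.logical(is_imf(tone(10, dur = 1))))
  expect_false(as.logical(is_imf(tone(10, dur = 1) + 10)))
  expect_false(as.logical(is_imf(tone(3, dur = 2) + tone(30, dur = 2))))
})

test_that("sifting a pure tone converges quickly to itself", {
  x <- tone(10, dur = 4)
  res <- extract_imf(x)
  cw <- viemdar:::central_window(length(x), 0.8)
  rel <- sqrt(sum((res$c[cw] - x[cw])^2) / sum(x[cw]^2))
  expect_lt(rel, 0.05)
  expect_lte(res$sift_count, 5)
})

test_that("sifting a two-tone mixture extracts the fast tone first", {
  tt <- two_tone()
  res <- extract_imf(tt$hi + tt$lo)
  cw <- viemdar:::central_window(4000, 0.8)
  expect_gt(cor(res$c[cw], tt$hi[cw]), 0.95)
  cfg <- sift_config(max_sifts = 3)
  expect_lte(extract_imf(tt$hi + tt$lo, cfg)$sift_count, 3)
})

test_that("decomposition recombines exactly and orders modes by frequency", {
  t <- seq(0, 4 - 1e-3, by = 1e-3)
  x <- tone(10) + tone(1, phase = 0.3) + 0.5 * t
  d <- emd_decompose(x)
  expect_gte(d$n, 2)
  expect_lt(max(abs(emd_reconstruct(d) - x)), 1e-9 * max(abs(x)))

  # dominant FFT bin of IMF1 in the 10 Hz octave, IMF2 near 1 Hz
  peak_hz <- function(c) (which.max(Mod(stats::fft(c))[2:2000])) * 1000 / 4000
  expect_gt(peak_hz(d$imfs[[1]]), 5)
  expect_lt(peak_hz(d$imfs[[2]]), 5)
  # residual tracks the trend
  expect_gt(cor(d$residual, t), 0.85)

  # mean instantaneous frequency non-increasing across modes
  freqs <- vapply(d$imfs, mean_inst_freq, numeric(1), fs = 1000)
  expect_true(all(diff(freqs) <= 1e-6))
})

test_that("degenerate inputs give zero IMFs and preprocessed epochs a plausible count", {
  d <- emd_decompose(rep(3, 100))
  expect_equal(d$n, 0)
  expect_equal(d$residual, rep(3, 100))

  pp <- synth_preprocessed()
  x <- viemdar:::trial_matrix(pp, 1)["FP2", ]
  d2 <- emd_decompose(x)
  expect_gte(d2$n, 4)
  expect_lte(d2$n, 12)
})

test_that("decomposition is capped at max_imfs with a warning", {
  set.seed(7)
  x <- stats::rnorm(2048)
  expect_warning(d <- emd_decompose(x, sift_config(max_imfs = 2)),
                 "max_imfs")
  expect_equal(d$n, 2)
  expect_lt(max(abs(emd_reconstruct(d) - x)), 1e-9 * max(abs(x)))
})
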