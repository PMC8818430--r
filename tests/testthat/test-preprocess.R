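test_that("linear correction annihilates lines and preserves oscillations", {
  expect_equal(linear_correct(c(0, 1, 2, 3)), rep(0, 4))
  expect_equal(linear_correct(rep(7, 10)), rep(0, 10))
  expect_error(linear_correct(3), "2 samples")

  t <- seq(0, 1 - 1e-3, by = 1e-3)
  x <- sin(2 * pi * 10 * t) + 0.5 * t
  y <- linear_correct(x)
  refit <- stats::lm(y ~ t)
  expect_lt(abs(stats::coef(refit)[2]) / 1000, 1e-9)   # slope per sample
  expect_gt(cor(y, sin(2 * pi * 10 * t)), 0.99)
})

test_that("elliptic band-pass passes alpha and rejects neighbours", {
  fs <- 1000
  t <- seq(1 / fs, 4, by = 1 / fs)
  mid <- 1001:3000
  rms <- function(v) sqrt(mean(v^2))

  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_elliptic(x10, fs)
  # the observed gain must match the design's frequency response at 10 Hz
  # (double pass), evaluated independently from the biquad sections
  sos <- viemdar:::design_ellip_bandpass(fs, c(8, 13), 0.5, 50)
  w <- exp(-1i * 2 * pi * 10 / fs)
  H1 <- prod(vapply(sos$sections, function(s)
    abs(sum(s$b * w^(0:2)) / sum(s$a * w^(0:2))), numeric(1))) * abs(sos$gain)
  gain2 <- H1^2                                 # forward-backward
  obs <- rms(y10[mid]) / rms(x10[mid])
  expect_lt(abs(obs - gain2), 0.02)
  expect_lt(20 * log10(1 / obs), 1)             # < 1 dB net loss at 10 Hz

  for (f in c(4, 25)) {
    y <- bandpass_elliptic(sin(2 * pi * f * t), fs)
    expect_gt(20 * log10(1 / rms(y[mid])), 40)
  }
  y50 <- bandpass_elliptic(sin(2 * pi * 50 * t), fs)
  expect_lt(rms(y50[mid]), 0.01)

  expect_equal(bandpass_elliptic(numeric(4000), fs), numeric(4000))
  expect_error(bandpass_elliptic(x10, fs, band = c(8, 600)), "fs/2")
})

test_that("notch filter suppresses 50 Hz and spares 10 Hz", {
  fs <- 1000
  t <- seq(1 / fs, 4, by = 1 / fs)
  mid <- 1001:3000
  y50 <- notch_filter(sin(2 * pi * 50 * t), fs)
  expect_lt(sqrt(mean(y50[mid]^2)), 0.01)
  y10 <- notch_filter(sin(2 * pi * 10 * t), fs)
  expect_gt(sqrt(mean(y10[mid]^2)), 0.95 * sqrt(0.5))
})

test_that("artifact rejection is inert on clean data and removes spikes", {
  set.seed(21)
  n <- 2000
  X <- matrix(stats::rnorm(8 * n), nrow = 8,
              dimnames = list(VI_CHANNELS, NULL))
  rec <- eeg_recording(X, 1000, VI_CHANNELS)
  clean <- reject_artifact_components(rec, kurtosis_z = 5)
  expect_lt(max(abs(clean$data - rec$data)), 1e-6)

  # inject a sparse spike train into the frontal channels
  spikes <- numeric(n)
  spikes[sample(n, 12)] <- 40
  Xa <- X
  Xa["FP2", ] <- Xa["FP2", ] + spikes
  Xa["F8", ] <- Xa["F8", ] + 0.8 * spikes
  reca <- eeg_recording(Xa, 1000, VI_CHANNELS)
  k_before <- viemdar:::sample_kurtosis(Xa["FP2", ])
  cleaned <- reject_artifact_components(reca, kurtosis_z = 3)
  k_after <- viemdar:::sample_kurtosis(cleaned$data["FP2", ])
  expect_lt(k_after, k_before)
  expect_equal(dim(cleaned$data), dim(Xa))

  # second pass changes nothing appreciably
  twice <- reject_artifact_components(cleaned, kurtosis_z = 3)
  expect_lt(max(abs(twice$data - cleaned$data)), 1e-6)

  expect_error(reject_artifact_components(reca, n_components = 9),
               "n_components")
})

test_that("epoching extracts windows at onsets and validates ranges", {
  fs <- 1000
  X <- matrix(seq_len(2 * 12 * fs), nrow = 2)
  rec <- eeg_recording(X, fs, c("FP2", "F8"))
  ts <- epoch_recording(rec, onsets = c(1, 7), labels = c("static", "moving"),
                        window = c(0, 4))
  expect_equal(dim(ts$trials), c(2, 2, 4000))
  expect_equal(ts$trials[1, 1, 1], X[1, fs + 1])

  empty <- epoch_recording(rec, numeric(0), character(0))
  expect_equal(dim(empty$trials)[1], 0)

  expect_error(epoch_recording(rec, 11, "static"), "trial 1")
})

test_that("preprocessing preserves shape and removes drift and line noise", {
  ds <- generate_dataset(synth_config(n_trials_per_class = 2, seed = 8,
                                      drift_amp = 30, line_amp = 10))
  pp <- preprocess_trialset(ds)
  expect_equal(dim(pp$trials), dim(ds$trials))
  expect_true(all(is.finite(pp$trials)))
  x <- viemdar:::trial_matrix(pp, 1)["FP2", ]
  expect_lt(band_power(x, c(45, 55), fs = 1000),
            0.01 * band_power(x, "alpha"))

  ppn <- preprocess_trialset(ds, path = "notch")
  xn <- viemdar:::trial_matrix(ppn, 1)["FP2", ]
  # notch path keeps theta/beta energy that the band-pass would kill
  expect_gt(band_power(xn, "beta"), band_power(x, "beta"))
})
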