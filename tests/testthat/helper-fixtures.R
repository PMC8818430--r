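# shared fixture builders; everything generated in code, fixed seeds

tone <- function(freq, fs = 1000, dur = 4, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

two_tone <- function(f_hi = 10, f_lo = 1, a_hi = 1, a_lo = 1, fs = 1000,
                     dur = 4) {
  list(hi = tone(f_hi, fs, dur, a_hi),
       lo = tone(f_lo, fs, dur, a_lo, phase = 0.3))
}

# a small preprocessed synthetic dataset, memoised per options
synth_preprocessed <- local({
  cache <- list()
  function(n_per_class = 5, seed = 42, alpha_contrast = 1, ...) {
    key <- paste(n_per_class, seed, alpha_contrast, ...)
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_trials_per_class = n_per_class, seed = seed,
                          alpha_contrast = alpha_contrast, ...)
      cache[[key]] <<- preprocess_trialset(generate_dataset(cfg))
    }
    cache[[key]]
  }
})

# independent reference EMD (separate implementation, run through python)
reference_emd <- function(x) {
  script <- system.file("oracle", "emd_reference.py", package = "viemdar")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(sprintf("%.10e", x), tf)
  out <- system2("python", c(script, tf), stdout = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(out), " +"), as.numeric))
  list(imfs = lapply(seq_len(ncol(m) - 1), function(j) m[, j]),
       residual = m[, ncol(m)], n = ncol(m) - 1)
}

# mean instantaneous frequency (Hz) of an IMF over the central 80%
mean_inst_freq <- function(c, fs) {
  az <- hilbert_analytic(c)
  th <- signal::unwrap(az$theta)
  cw <- viemdar:::central_window(length(c), 0.8)
  mean(diff(th[cw])) * fs / (2 * pi)
}

# simulate a stationary AR(p) series in the y(i) = sum phi_j y(i-j) + n(i)
# convention
sim_ar <- function(phi, n, sd = 1, seed = 1, burn = 500) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd, n.start = burn))
}
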