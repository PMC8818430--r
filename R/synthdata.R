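#' Default EEG channel montage
#'
#' The eight-channel montage used throughout: two frontal channels carrying
#' the class contrast, three central and three occipital channels.
#' @export
VI_CHANNELS <- c("FP2", "F8", "C3", "Cz", "C4", "O1", "Oz", "O2")

#' Configuration for the synthetic visual-imagery EEG generator
#'
#' The generator emulates a two-class visual-imagery experiment: per trial a
#' 4 s, 1,000 Hz multichannel epoch. Both classes carry an 8-13 Hz alpha
#' oscillation on the frontal channels FP2 and F8 (and a stronger,
#' class-independent one on the occipital channels); the "moving" class
#' additionally amplitude-modulates the frontal alpha with a slow (0.5 Hz)
#' periodic ramp-and-hold envelope scaled by `alpha_contrast`. The
#' modulation is centred so it perturbs mean alpha power only mildly: the
#' class contrast is carried chiefly by the nonstationary envelope
#' structure, which is what the hybrid EMD+AR features target. All channels carry 1/f-shaped
#' background noise, a 50 Hz line component with random phase, and a linear
#' drift. At `alpha_contrast = 0` the two classes are drawn from identical
#' distributions.
#'
#' @param n_trials_per_class Trials per class (default 100).
#' @param n_channels Number of channels, 1..8; the first `n_channels` labels
#'   of [VI_CHANNELS] are used.
#' @param fs Sampling rate in Hz.
#' @param epoch_s Epoch length in seconds; `fs * epoch_s` must be an integer.
#' @param alpha_contrast Dimensionless effect size >= 0 scaling the
#'   alpha-band amplitude modulation of the "moving" class on FP2/F8.
#' @param alpha_amp Mean alpha amplitude on FP2/F8 in microvolts.
#' @param amp_jitter_sd SD of the per-trial log-normal amplitude jitter
#'   (on the log scale) shared by both classes.
#' @param noise_sd Background 1/f noise SD in microvolts.
#' @param noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param line_amp 50 Hz line amplitude in microvolts.
#' @param drift_amp Peak linear drift over the epoch in microvolts.
#' @param artifact_rate Expected number of large low-frequency frontal
#'   artifact transients per trial (0 disables the injector).
#' @param seed Integer RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 100L, n_channels = 8L,
                         fs = 1000, epoch_s = 4, alpha_contrast = 1,
                         alpha_amp = 22, amp_jitter_sd = 0.15,
                         noise_sd = 8, noise_exponent = 1,
                         line_amp = 2, drift_amp = 5,
                         artifact_rate = 0, seed = 1L) {
  stopifnot(n_trials_per_class >= 1, n_channels >= 1, n_channels <= 8,
            fs > 0, epoch_s > 0, alpha_contrast >= 0, noise_sd >= 0,
            line_amp >= 0, drift_amp >= 0)
  n_samp <- fs * epoch_s
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("synth_config: fs * epoch_s must be an integer number of samples")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels),
                 channel_labels = VI_CHANNELS[seq_len(n_channels)],
                 fs = fs, epoch_s = epoch_s, n_samples = as.integer(round(n_samp)),
                 alpha_contrast = alpha_contrast, alpha_amp = alpha_amp,
                 amp_jitter_sd = amp_jitter_sd, noise_sd = noise_sd,
                 noise_exponent = noise_exponent, line_amp = line_amp,
                 drift_amp = drift_amp, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# deterministic per-trial substream: stable under changes to trial counts
trial_seed <- function(seed, trial_index) {
  as.integer((as.double(seed) * 7919 + as.double(trial_index) * 104729) %%
               2147483629)
}

# 1/f^a-shaped Gaussian noise via spectral shaping of white noise
pink_noise <- function(n, sd, exponent) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                    # avoid DC blow-up
  f <- pmin(f, n - f + 1)                      # symmetric frequency index
  shape <- 1 / f^(exponent / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# slow periodic (0.5 Hz) ramp-and-hold amplitude modulation: within each
# 2 s cycle the envelope ramps up over the first second and holds over the
# second. Centred near zero so the modulation changes the temporal structure
# of the alpha envelope much more than its mean power: the class contrast is
# then carried mainly by nonstationarity, not by gross band power.
ramp_hold <- function(t) {
  u <- (t * 0.5) %% 1
  pmin(1, 2 * u) - 0.65
}

#' Generate one synthetic EEG trial
#'
#' @param cfg A [synth_config()].
#' @param class_label `"static"` or `"moving"`.
#' @param trial_index Integer used to derive the per-trial RNG substream;
#'   trial `k` is reproducible independently of how many trials surround it.
#' @return Numeric matrix, channel x sample, in microvolts, with channel
#'   labels as rownames.
#' @export
generate_trial <- function(cfg, class_label, trial_index = 1L) {
  if (!class_label %in% c("static", "moving"))
    stop("generate_trial: class_label must be 'static' or 'moving'")
  n <- cfg$n_samples
  t <- seq(0, by = 1 / cfg$fs, length.out = n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(trial_seed(cfg$seed, trial_index))

  out <- matrix(0, nrow = cfg$n_channels, ncol = n,
                dimnames = list(cfg$channel_labels, NULL))
  # shared per-trial draws
  alpha_f <- stats::runif(1, 8.5, 12.5)          # per-trial alpha frequency
  alpha_ph <- stats::runif(1, 0, 2 * pi)
  amp <- cfg$alpha_amp * exp(stats::rnorm(1, 0, cfg$amp_jitter_sd))
  line_ph <- stats::runif(1, 0, 2 * pi)
  for (ch in seq_len(cfg$n_channels)) {
    lab <- cfg$channel_labels[ch]
    x <- pink_noise(n, cfg$noise_sd, cfg$noise_exponent)
    if (cfg$line_amp > 0)
      x <- x + cfg$line_amp * sin(2 * pi * 50 * t + line_ph)
    if (cfg$drift_amp > 0)
      x <- x + stats::runif(1, -1, 1) * cfg$drift_amp * (t / cfg$epoch_s)
    if (lab %in% c("FP2", "F8")) {
      env <- amp
      if (class_label == "moving" && cfg$alpha_contrast > 0)
        env <- amp * (1 + cfg$alpha_contrast * ramp_hold(t))
      x <- x + env * sin(2 * pi * alpha_f * t + alpha_ph)
    } else if (lab %in% c("O1", "Oz", "O2")) {
      # class-independent occipital alpha
      x <- x + 1.5 * amp * sin(2 * pi * alpha_f * t + alpha_ph +
                                 stats::runif(1, 0, 2 * pi))
    }
    if (cfg$artifact_rate > 0 && lab %in% c("FP2", "F8")) {
      n_art <- stats::rpois(1, cfg$artifact_rate)
      for (a in seq_len(n_art)) {
        centre <- stats::runif(1, 0.2, cfg$epoch_s - 0.2)
        width <- 0.15
        x <- x + 20 * cfg$alpha_amp * exp(-((t - centre)^2) / (2 * width^2))
      }
    }
    out[ch, ] <- x
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full synthetic trial set
#'
#' Generates `2 * n_trials_per_class` trials (classes "static" and "moving"),
#' shuffles their order deterministically from the config seed, and packages
#' them as a `trial_set` with the generating config attached for provenance.
#'
#' @param cfg A [synth_config()].
#' @return A [trial_set()] with an extra `config` element.
#' @export
generate_dataset <- function(cfg) {
  n_tot <- 2L * cfg$n_trials_per_class
  labels <- rep(c("static", "moving"), each = cfg$n_trials_per_class)
  trials <- array(0, dim = c(n_tot, cfg$n_channels, cfg$n_samples))
  for (k in seq_len(n_tot))
    trials[k, , ] <- generate_trial(cfg, labels[k], trial_index = k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(trial_seed(cfg$seed, 0L))
  ord <- sample.int(n_tot)
  ts <- trial_set(trials[ord, , , drop = FALSE], labels[ord], cfg$fs,
                  cfg$channel_labels, window = c(0, cfg$epoch_s))
  ts$config <- cfg
  ts
}
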