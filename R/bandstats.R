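#' Conventional EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz.
#' @export
EEG_BANDS <- data.frame(
  name = c("delta", "theta", "alpha", "beta", "gamma"),
  low_hz = c(0.5, 4, 8, 13, 30),
  high_hz = c(4, 8, 13, 30, 80),
  stringsAsFactors = FALSE
)

#' Band power of one channel of a trial
#'
#' Mean power (microvolt^2) in the band from a Hann-tapered periodogram of
#' the whole epoch, normalised so that summing over all bins returns the
#' signal's mean square (Parseval, window-compensated).
#'
#' @param trial Channel x sample matrix with channel rownames, or a numeric
#'   vector.
#' @param band Two-element numeric `c(low, high)` in Hz, or a band name from
#'   [EEG_BANDS].
#' @param channel Channel label (ignored for vector input).
#' @param fs Sampling rate in Hz.
#' @return Non-negative scalar.
#' @export
band_power <- function(trial, band, channel = NULL, fs = 1000) {
  if (is.character(band)) {
    row <- EEG_BANDS[EEG_BANDS$name == band, ]
    if (!nrow(row)) stop("band_power: unknown band name ", band)
    band <- c(row$low_hz, row$high_hz)
  }
  if (band[1] <= 0 || band[2] > fs / 2)
    stop("band_power: band outside (0, fs/2)")
  x <- if (is.matrix(trial)) {
    if (is.null(channel) || !channel %in% rownames(trial))
      stop("band_power: channel not found")
    trial[channel, ]
  } else trial
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hann taper
  U <- mean(w^2)
  P <- Mod(stats::fft(x * w))^2 / (n^2 * U)             # sum(P) == mean(x^2)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  in_band <- half & freqs >= band[1] & freqs <= band[2]
  2 * sum(P[in_band])                                   # fold negative freqs
}

#' Two-sample test of band power between classes
#'
#' Welch's two-sided two-sample t-test.
#'
#' @param powers_a,powers_b Numeric vectors (>= 2 each).
#' @return The p-value.
#' @export
class_ttest <- function(powers_a, powers_b) {
  stopifnot(length(powers_a) >= 2, length(powers_b) >= 2)
  if (stats::sd(powers_a) == 0 && stats::sd(powers_b) == 0) {
    if (isTRUE(all.equal(mean(powers_a), mean(powers_b)))) return(1)
    stop("class_ttest: degenerate variance in both groups")
  }
  stats::t.test(powers_a, powers_b)$p.value
}

#' Per-channel two-way ANOVA of band power
#'
#' For each channel, a fixed-effects two-way ANOVA of band power on
#' task (class) and frequency band, reporting the task effect's p-value and
#' degrees of freedom. The design must be balanced (every class x band cell
#' observed equally often per channel).
#'
#' @param band_powers Data frame with columns `class`, `band`, `channel`,
#'   `power` (one row per trial x band x channel observation).
#' @return Data frame with columns `channel`, `task_df`, `task_p`.
#' @export
band_anova <- function(band_powers) {
  stopifnot(all(c("class", "band", "channel", "power") %in%
                  names(band_powers)))
  out <- lapply(unique(band_powers$channel), function(ch) {
    d <- band_powers[band_powers$channel == ch, ]
    tab <- table(d$class, d$band)
    if (length(unique(as.vector(tab))) != 1 || any(tab == 0)) {
      miss <- which(tab == 0, arr.ind = TRUE)
      stop("band_anova: unbalanced design for channel ", ch,
           if (nrow(miss)) paste0("; empty cells: ",
                                  paste(rownames(tab)[miss[, 1]],
                                        colnames(tab)[miss[, 2]],
                                        sep = ":", collapse = ", ")))
    }
    d$class <- factor(d$class)
    d$band <- factor(d$band)
    fit <- stats::aov(power ~ class * band, data = d)
    s <- summary(fit)[[1]]
    i <- grep("^class\\s*$", rownames(s))
    data.frame(channel = ch, task_df = s$Df[i], task_p = s$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-band, per-channel class-difference table
#'
#' Computes band power for every trial, channel and band on the
#' notch-only-preprocessed trial set, runs [class_ttest()] per
#' (channel, band), and [band_anova()] per channel. This mirrors the usual
#' reporting layout: an 8-channel x 5-band grid of t-test p-values plus the
#' per-channel ANOVA task p and df.
#'
#' @param ts A [trial_set()] preprocessed with `path = "notch"` (the
#'   band-pass would annihilate all non-alpha bands).
#' @param bands Band definition data frame, as [EEG_BANDS].
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust the t-test p-values
#'   across the grid (off by default).
#' @return List with `ttest` (channels x bands matrix of p-values),
#'   `anova` (data frame from [band_anova()]) and `powers` (long data frame).
#' @export
band_stats_table <- function(ts, bands = EEG_BANDS, adjust = FALSE) {
  chs <- ts$channel_labels
  n_trials <- dim(ts$trials)[1]
  rows <- vector("list", n_trials * length(chs) * nrow(bands))
  r <- 0L
  for (k in seq_len(n_trials)) {
    m <- trial_matrix(ts, k)
    for (ch in chs) {
      for (b in seq_len(nrow(bands))) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          trial = k, class = ts$labels[k], channel = ch,
          band = bands$name[b],
          power = band_power(m[ch, ], c(bands$low_hz[b], bands$high_hz[b]),
                             fs = ts$fs),
          stringsAsFactors = FALSE)
      }
    }
  }
  powers <- do.call(rbind, rows)
  pmat <- matrix(NA_real_, length(chs), nrow(bands),
                 dimnames = list(chs, bands$name))
  for (ch in chs) {
    for (b in bands$name) {
      sel <- powers$channel == ch & powers$band == b
      pa <- powers$power[sel & powers$class == "static"]
      pb <- powers$power[sel & powers$class == "moving"]
      pmat[ch, b] <- class_ttest(pa, pb)
    }
  }
  if (adjust) pmat[] <- stats::p.adjust(pmat, method = "BH")
  anova <- band_anova(powers)
  list(ttest = pmat, anova = anova, powers = powers)
}
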