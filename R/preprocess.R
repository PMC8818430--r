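#' Remove the least-squares linear trend
#'
#' Subtracts the straight-line least-squares fit, leaving a zero-mean,
#' zero-slope residual.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
linear_correct <- function(x) {
  n <- length(x)
  if (n < 2) stop("linear_correct: need at least 2 samples")
  i <- seq_len(n) - (n + 1) / 2               # centred index: orthogonal basis
  slope <- sum(i * x) / sum(i * i)
  x - mean(x) - slope * i
}

# Elliptic band-pass designed in zero-pole-gain form and factored into
# second-order sections. The direct polynomial form is numerically singular
# at 8-13 Hz / 1 kHz (normalised band ~0.02), so the analog low-pass
# prototype is transformed and bilinearly mapped while still factored, and
# the filter is applied as a biquad cascade.
design_ellip_bandpass <- function(fs, band, rp, rs, transition = 1) {
  wp <- band / (fs / 2)
  ws <- c(band[1] - transition, band[2] + transition) / (fs / 2)
  ord <- signal::ellipord(Wp = wp, Ws = ws, Rp = rp, Rs = rs)
  TT <- 2
  Ww <- 2 / TT * tan(pi * ord$Wc / TT)
  zpg <- utils::getFromNamespace("ncauer", "signal")(rp, rs, ord$n)
  zpg <- signal::sftrans(zpg, W = Ww, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = TT)
  sos <- zpg_to_sos(zpg)
  sos$order <- ord$n
  sos
}

# factor a z-plane zero-pole-gain filter into biquads, pairing conjugate
# poles with their nearest zeros
zpg_to_sos <- function(zpg) {
  z <- zpg$zero
  p <- zpg$pole
  if (length(z) < length(p)) z <- c(z, rep(0 + 0i, length(p) - length(z)))
  p <- p[order(-Mod(p))]
  used_z <- rep(FALSE, length(z))
  used_p <- rep(FALSE, length(p))
  sections <- list()
  while (any(!used_p)) {
    i <- which(!used_p)[1]
    used_p[i] <- TRUE
    pp <- p[i]
    j <- which(!used_p & Mod(p - Conj(p[i])) < 1e-8)[1]
    if (!is.na(j)) {
      used_p[j] <- TRUE
      pp <- c(pp, p[j])
    }
    zz <- complex(0)
    for (k in seq_along(pp)) {
      idx <- which(!used_z)
      if (!length(idx)) break
      jz <- idx[which.min(Mod(z[idx] - pp[k]))]
      used_z[jz] <- TRUE
      zz <- c(zz, z[jz])
    }
    b <- Re(signal::poly(zz))
    a <- Re(signal::poly(pp))
    sections[[length(sections) + 1L]] <-
      list(b = c(b, rep(0, 3 - length(b))), a = c(a, rep(0, 3 - length(a))))
  }
  list(sections = sections, gain = Re(zpg$gain))
}

sos_filtfilt <- function(sos, x) {
  for (s in sos$sections)
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  x * sos$gain^2
}

# simple memoisation: the design depends only on (fs, band, rp, rs)
.filter_cache <- new.env(parent = emptyenv())

#' Zero-phase elliptic band-pass filter
#'
#' Minimum-order elliptic IIR design with the stated passband ripple and
#' stopband attenuation (transition edges 1 Hz outside the passband),
#' applied forward-backward so the net phase is zero; the effective
#' attenuation in dB therefore doubles.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz, > 2 x upper band edge.
#' @param band Passband edges in Hz (default `c(8, 13)`).
#' @param rp Passband ripple in dB.
#' @param rs Stopband attenuation in dB.
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_elliptic <- function(x, fs, band = c(8, 13), rp = 0.5, rs = 50) {
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("bandpass_elliptic: band must lie inside (0, fs/2)")
  stopifnot(all(is.finite(x)))
  key <- paste0("bp_", fs, "_", band[1], "_", band[2], "_", rp, "_", rs)
  sos <- .filter_cache[[key]]
  if (is.null(sos)) {
    sos <- design_ellip_bandpass(fs, band, rp, rs)
    .filter_cache[[key]] <- sos
  }
  sos_filtfilt(sos, x)
}

#' Zero-phase 50 Hz IIR notch filter
#'
#' Second-order notch (pole radius set by `q`), applied forward-backward.
#' Intended for the analysis path that bypasses the 8-13 Hz band-pass
#' (per-band statistics), where line noise must still be suppressed.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param f0 Notch frequency in Hz.
#' @param q Quality factor; bandwidth is `f0 / q`.
#' @return Filtered numeric vector.
#' @export
notch_filter <- function(x, fs, f0 = 50, q = 30) {
  if (f0 <= 0 || f0 >= fs / 2) stop("notch_filter: f0 must be in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  r <- 1 - (w0 / q) / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)                     # unit gain at DC
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

# --- ICA-based artifact rejection -----------------------------------------

# symmetric FastICA with tanh nonlinearity; deterministic given seed
fastica_decompose <- function(X, n_components, seed = 1L, max_iter = 200,
                              tol = 1e-6) {
  # X: channel x sample
  nc <- nrow(X)
  Xc <- X - rowMeans(X)
  cv <- Xc %*% t(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12))) %*% t(eg$vectors[, keep])
  Z <- K %*% Xc                                # whitened
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(n_components^2), n_components)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W
    W1 <- sym_orth(W1)
    if (max(abs(abs(diag(W1 %*% t(W))) - 1)) < tol) {
      W <- W1
      break
    }
    W <- W1
  }
  S <- W %*% Z                                 # sources x sample
  unmix <- W %*% K                             # sources = unmix %*% Xc
  mix <- MASS_ginv(unmix)                      # channels x sources
  list(S = S, mix = mix, means = rowMeans(X))
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency)
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*%
    diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Remove high-kurtosis independent components
#'
#' Decomposes the recording into statistically independent components
#' (negentropy-maximising ICA, deterministic given `seed`), zeroes every
#' component whose sample-kurtosis z-score across components exceeds
#' `kurtosis_z`, and reconstructs. The z-score is robust
#' (median/MAD-based): with only a handful of components, a moment-based
#' z-score is bounded by `(n-1)/sqrt(n)` and an outlying artifact component
#' could never reach a usable threshold. Transient artifacts (blinks,
#' spikes) concentrate in heavy-tailed components, which this flags; if no
#' component exceeds the threshold the input is returned unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param kurtosis_z Rejection threshold on the kurtosis z-score.
#' @param n_components Number of components, <= channel count.
#' @param seed Seed for the ICA initialisation.
#' @return An [eeg_recording()] of identical shape.
#' @export
reject_artifact_components <- function(rec, kurtosis_z = 5,
                                       n_components = nrow(rec$data),
                                       seed = 1L) {
  X <- rec$data
  if (nrow(X) < 2) stop("reject_artifact_components: need >= 2 channels")
  if (ncol(X) <= nrow(X))
    stop("reject_artifact_components: need more samples than channels")
  if (n_components > nrow(X))
    stop("reject_artifact_components: n_components exceeds channel count")
  dec <- fastica_decompose(X, n_components, seed = seed)
  k <- apply(dec$S, 1, sample_kurtosis)
  s <- stats::mad(k)
  if (s == 0) s <- stats::sd(k)
  z <- (k - stats::median(k)) / s
  bad <- which(z > kurtosis_z)
  if (!length(bad)) return(rec)
  S <- dec$S
  S[bad, ] <- 0
  Xr <- dec$mix %*% S + dec$means
  dimnames(Xr) <- dimnames(X)
  eeg_recording(Xr, rec$fs, rec$channel_labels, rec$t0)
}

#' Extract fixed-length epochs from a recording
#'
#' @param rec An [eeg_recording()].
#' @param onsets Onset times in seconds (relative to the recording start).
#' @param labels Per-onset class labels.
#' @param window Epoch window in seconds relative to each onset.
#' @return A [trial_set()]; trial order follows onset order.
#' @export
epoch_recording <- function(rec, onsets, labels, window = c(0, 4)) {
  stopifnot(length(onsets) == length(labels))
  n_samp <- round(diff(window) * rec$fs)
  n_tot <- ncol(rec$data)
  trials <- array(0, dim = c(length(onsets), nrow(rec$data), n_samp))
  for (k in seq_along(onsets)) {
    i0 <- round((onsets[k] + window[1]) * rec$fs) + 1L
    i1 <- i0 + n_samp - 1L
    if (i0 < 1 || i1 > n_tot)
      stop(sprintf("epoch_recording: trial %d window [%g, %g] s outside recording",
                   k, onsets[k] + window[1], onsets[k] + window[2]))
    trials[k, , ] <- rec$data[, i0:i1]
  }
  trial_set(trials, labels, rec$fs, rec$channel_labels, window = window)
}

#' Preprocess an epoched trial set
#'
#' Applies, per trial and channel, the fixed order: linear correction, then
#' the 8-13 Hz zero-phase elliptic band-pass (or, on the `"notch"` path, a
#' 50 Hz notch only), then optional ICA artifact rejection across channels.
#'
#' @param ts A [trial_set()].
#' @param band Passband in Hz, or `NULL` to skip the band-pass.
#' @param path `"bandpass"` (default analysis path) or `"notch"` (band
#'   statistics path: linear correction + 50 Hz notch, no band-pass).
#' @param reject_artifacts If `TRUE`, run [reject_artifact_components()]
#'   per trial.
#' @param kurtosis_z Rejection threshold when artifact rejection is on.
#' @param seed Seed for ICA initialisation.
#' @return A preprocessed [trial_set()] of identical shape.
#' @export
preprocess_trialset <- function(ts, band = c(8, 13),
                                path = c("bandpass", "notch"),
                                reject_artifacts = FALSE, kurtosis_z = 5,
                                seed = 1L) {
  path <- match.arg(path)
  out <- ts
  n_trials <- dim(ts$trials)[1]
  for (k in seq_len(n_trials)) {
    m <- trial_matrix(ts, k)
    for (ch in seq_len(nrow(m))) {
      x <- linear_correct(m[ch, ])
      x <- if (path == "bandpass") bandpass_elliptic(x, ts$fs, band)
           else notch_filter(x, ts$fs)
      m[ch, ] <- x
    }
    if (reject_artifacts && nrow(m) >= 2) {
      rec <- eeg_recording(m, ts$fs, ts$channel_labels)
      m <- reject_artifact_components(rec, kurtosis_z, seed = seed)$data
    }
    out$trials[k, , ] <- m
  }
  out$pipeline <- c("linear_correct",
                    if (path == "bandpass") "bandpass_elliptic"
                    else "notch_filter",
                    if (reject_artifacts) "reject_artifact_components")
  out
}
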