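#' Discrete analytic signal of an intrinsic mode function
#'
#' Frequency-domain construction: negative frequencies zeroed, positive
#' doubled, DC (and Nyquist for even lengths) kept. Returns the IMF, its
#' Hilbert transform, and the instantaneous amplitude and phase, with
#' `a^2 = c^2 + y^2` pointwise.
#'
#' @param c Numeric vector, length >= 8; approximately zero-mean (IMFs are).
#' @return An object of class `analytic_imf`: list with `c`, `y`, `a`
#'   (amplitude, >= 0) and `theta` (phase in `(-pi, pi]`).
#' @export
hilbert_analytic <- function(c) {
  n <- length(c)
  stopifnot(n >= 8)
  if (all(c == 0)) {
    return(structure(list(c = c, y = c, a = c, theta = c),
                     class = "analytic_imf"))
  }
  H <- stats::fft(c)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(H * h, inverse = TRUE) / n
  y <- Im(z)
  a <- Mod(z)
  theta <- Arg(z)
  theta[theta <= -pi] <- pi                   # keep phase in (-pi, pi]
  structure(list(c = c, y = y, a = a, theta = theta), class = "analytic_imf")
}

#' Mean instantaneous energy of an amplitude envelope
#'
#' Mean of `a(t)^2` over the central fraction of samples; the edges are
#' trimmed because the discrete Hilbert transform distorts them.
#'
#' @param a Non-negative amplitude sequence.
#' @param central_fraction Fraction of samples kept, centred.
#' @return Non-negative scalar.
#' @export
mean_instantaneous_energy <- function(a, central_fraction = 0.8) {
  if (!length(a)) stop("mean_instantaneous_energy: empty input")
  stopifnot(all(is.finite(a)), all(a >= 0))
  mean(a[central_window(length(a), central_fraction)]^2)
}

#' Hilbert-Huang instantaneous-energy features for one trial
#'
#' Per named channel: EMD-decompose the signal, take the first `k_imfs`
#' IMFs (zero-filling missing slots), compute the mean instantaneous energy
#' of each IMF's Hilbert amplitude, and concatenate channel-major.
#'
#' @param trial Channel x sample matrix with channel rownames.
#' @param channels Channels to extract from (default FP2 and F8).
#' @param k_imfs Number of IMF energy slots per channel.
#' @param cfg A [sift_config()].
#' @param decomps Optional pre-computed list of `imf_decomposition`s named
#'   by channel (to share decompositions across feature extractors).
#' @param energy_stat `"mean_square"` (mean of `a^2`, default) or
#'   `"mean_amplitude"` (mean of `a`).
#' @return Named numeric vector of length `length(channels) * k_imfs`
#'   (names `FP2_E1`, ..., `F8_Ek`).
#' @export
hht_features <- function(trial, channels = c("FP2", "F8"), k_imfs = 4,
                         cfg = sift_config(), decomps = NULL,
                         energy_stat = c("mean_square", "mean_amplitude")) {
  energy_stat <- match.arg(energy_stat)
  missing_ch <- setdiff(channels, rownames(trial))
  if (length(missing_ch))
    stop("hht_features: missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  out <- numeric(0)
  for (ch in channels) {
    d <- if (!is.null(decomps)) decomps[[ch]]
         else emd_decompose(trial[ch, ], cfg)
    for (j in seq_len(k_imfs)) {
      if (j <= d$n && any(d$imfs[[j]] != 0)) {
        az <- hilbert_analytic(d$imfs[[j]])
        e <- if (energy_stat == "mean_square")
          mean_instantaneous_energy(az$a)
        else mean(az$a[central_window(length(az$a), 0.8)])
      } else {
        e <- 0
      }
      out <- c(out, e)
    }
  }
  names(out) <- as.vector(t(outer(channels, seq_len(k_imfs),
                                  function(ch, j) paste0(ch, "_E", j))))
  out
}
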