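#' Burg autoregressive fit
#'
#' Burg-recursion AR fit in the convention
#' `y(i) = sum_j phi_j y(i-j) + n(i)`: positive coefficients on past values.
#' Burg estimates minimise combined forward/backward prediction error, which
#' guarantees all roots of the characteristic polynomial lie strictly inside
#' the unit circle.
#'
#' @param x Numeric vector, length > 3p, not constant.
#' @param p Model order.
#' @param demean Subtract the sample mean first (default `TRUE`).
#' @return An object of class `ar_fit`: list with `order`, `coeffs` (phi),
#'   `resid_var` (final prediction-error power) and `method = "burg"`.
#' @export
burg_fit <- function(x, p, demean = TRUE) {
  if (length(unique(x)) == 1) stop("burg_fit: constant input")
  if (length(x) <= 3 * p) stop("burg_fit: need length > 3p")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = demean)
  structure(list(order = as.integer(p), coeffs = as.numeric(fit$ar),
                 resid_var = as.numeric(fit$var.pred), method = "burg"),
            class = "ar_fit")
}

#' AR order selection by the Akaike information criterion
#'
#' Fits orders `1..p_max` by Burg recursion and returns the order minimising
#' `AIC(p) = N log(resid_var(p)) + 2 p`; ties break to the smallest order.
#'
#' @param x Numeric vector, length > 3 p_max.
#' @param p_max Largest candidate order.
#' @return Selected integer order.
#' @export
aic_order <- function(x, p_max) {
  if (p_max >= length(x) / 3) stop("aic_order: p_max too large for series length")
  N <- length(x)
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p_max, demean = TRUE)
  # ar.burg exposes partialacf; recompute variance per order via Levinson
  # recursion on the reflection coefficients
  refl <- as.numeric(fit$partialacf)
  v <- stats::var(x) * (N - 1) / N
  aics <- numeric(p_max)
  for (p in seq_len(p_max)) {
    v <- v * (1 - refl[p]^2)
    aics[p] <- N * log(v) + 2 * p
  }
  which.min(aics)                              # which.min takes first on ties
}

#' Plain AR coefficient features for one trial
#'
#' Burg AR(`p`) per channel on the preprocessed series; the feature vector
#' concatenates the FP2 then F8 coefficients, named `FP2_AR1..FP2_ARp,
#' F8_AR1..F8_ARp` (12-dimensional at the default order 6).
#'
#' @param trial Channel x sample matrix with channel rownames.
#' @param p AR order (default 6).
#' @param channels Channels used (default FP2 and F8).
#' @return Named numeric vector of length `length(channels) * p`.
#' @export
ar_features <- function(trial, p = 6, channels = c("FP2", "F8")) {
  missing_ch <- setdiff(channels, rownames(trial))
  if (length(missing_ch))
    stop("ar_features: missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  out <- numeric(0)
  for (ch in channels) out <- c(out, burg_fit(trial[ch, ], p)$coeffs)
  names(out) <- as.vector(t(outer(channels, seq_len(p),
                                  function(ch, j) paste0(ch, "_AR", j))))
  out
}

# roots of the AR characteristic polynomial 1 - phi_1 z - ... - phi_p z^p
# (stationary iff all outside the unit circle in z, i.e. the companion
# eigenvalues are inside); returns companion-form eigenvalue moduli
ar_root_moduli <- function(coeffs) {
  p <- length(coeffs)
  if (p == 0) return(numeric(0))
  M <- matrix(0, p, p)
  M[1, ] <- coeffs
  if (p > 1) M[cbind(2:p, 1:(p - 1))] <- 1
  Mod(eigen(M, only.values = TRUE)$values)
}
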