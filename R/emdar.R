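#' Energy-normalise an intrinsic mode function
#'
#' Divides by the square root of the discrete energy `sum(c^2) * dt`, so the
#' returned sequence has unit energy (division by the L2 norm, the
#' conventional energy normalisation). With `literal = TRUE` the component
#' is instead divided by the energy itself — dimensionally not a
#' normalisation to unit energy, but retained as a variant since both forms
#' appear in the applied literature. An all-zero input (a zero-padded IMF
#' slot) is returned unchanged with attribute `zero_padded = TRUE`.
#'
#' @param c Numeric vector.
#' @param dt Sample interval in seconds.
#' @param literal Divide by the energy instead of its square root.
#' @return Numeric vector; with `literal = FALSE`,
#'   `sum(out^2) * dt == 1` (unless all-zero).
#' @export
energy_normalize <- function(c, dt = 1, literal = FALSE) {
  if (all(c == 0)) return(structure(c, zero_padded = TRUE))
  e <- sum(c^2) * dt
  if (literal) c / e else c / sqrt(e)
}

#' Pad decompositions to a common IMF count
#'
#' Given decompositions of several trials, finds the maximum IMF count `n`
#' and appends all-zero IMFs to every decomposition with fewer, so that
#' per-IMF feature blocks align across trials.
#'
#' @param decomps Non-empty list of `imf_decomposition` objects.
#' @return List of decompositions, all with `n` equal to the maximum count.
#' @export
pad_imf_count <- function(decomps) {
  stopifnot(length(decomps) >= 1)
  n_max <- max(vapply(decomps, function(d) as.integer(d$n), integer(1)))
  lapply(decomps, function(d) {
    if (d$n < n_max) {
      zeros <- rep(list(numeric(d$input_length)), n_max - d$n)
      d$imfs <- c(d$imfs, zeros)
      d$n <- n_max
    }
    d
  })
}

# least-squares design matrix fit of an AR(m) in the convention
# c(t) + sum_k h_k c(t-k) = e(t); rank-deficient designs (very smooth
# components whose lags are collinear) fall back to the minimum-norm
# least-squares solution
ls_ar_core <- function(x, m) {
  if (length(unique(x)) == 1) stop("ls_ar_fit: singular design matrix")
  N <- length(x)
  y <- x[(m + 1):N]
  X <- sapply(seq_len(m), function(k) x[(m + 1 - k):(N - k)])
  X <- matrix(X, ncol = m)
  qx <- qr(X)
  if (qx$rank == m) {
    phi <- qr.coef(qx, y)                      # y(t) = sum phi_k y(t-k) + e
  } else {
    phi <- as.numeric(MASS_ginv(X) %*% y)
  }
  resid <- y - X %*% phi
  list(h = -as.numeric(phi), e2 = mean(resid^2))
}

#' Least-squares AR fit of an energy-normalised IMF
#'
#' Ordinary least squares for the model
#' `c(t) + sum_k h_k c(t-k) = e(t)` (note the sign: `h = -phi` relative to
#' the usual AR convention). The residual variance `e2` is the mean squared
#' residual. A zero-padded (all-zero) IMF returns `h = 0`, `e2 = 0` by
#' convention.
#'
#' @param c Numeric vector (usually energy-normalised), length > 3m.
#' @param m Model order.
#' @return An object of class `imf_ar_eigenvector`: list with `h` (length
#'   `m`), `e2`, `m`, `zero_padded`.
#' @export
ls_ar_fit <- function(c, m) {
  if (all(c == 0)) {
    return(structure(list(h = numeric(m), e2 = 0, m = as.integer(m),
                          zero_padded = TRUE),
                     class = "imf_ar_eigenvector"))
  }
  if (length(c) <= 3 * m) stop("ls_ar_fit: need length > 3m")
  core <- ls_ar_core(c, m)
  structure(list(h = core$h, e2 = core$e2, m = as.integer(m),
                 zero_padded = FALSE),
            class = "imf_ar_eigenvector")
}

#' AR order selection by the final prediction error
#'
#' Least-squares fits for `m = 1..m_max`; returns the `m` minimising
#' `FPE(m) = resid_var(m) * (N + m + 1) / (N - m - 1)`; ties break small.
#'
#' @param c Numeric vector, length > 3 m_max.
#' @param m_max Largest candidate order.
#' @return Selected integer order.
#' @export
fpe_order <- function(c, m_max) {
  if (m_max >= length(c) / 3) stop("fpe_order: m_max too large for series length")
  N <- length(c)
  fpe <- vapply(seq_len(m_max), function(m) {
    ls_ar_core(c, m)$e2 * (N + m + 1) / (N - m - 1)
  }, numeric(1))
  which.min(fpe)
}

#' Variance-contribution screening of IMFs
#'
#' Computes, per IMF, the variance contribution rate
#' `var(c_i) / sum_k var(c_k) * 100` (residual excluded) and the Pearson
#' correlation with the original signal, and selects the smallest prefix of
#' IMFs whose cumulative contribution reaches `threshold` (at least
#' `min_keep`).
#'
#' @param decomp An `imf_decomposition` of `x`.
#' @param x The decomposed signal.
#' @param threshold Cumulative contribution target in percent.
#' @param min_keep Minimum number of IMFs selected.
#' @return An object of class `imf_screen_report`: data frame with columns
#'   `imf`, `contribution_pct`, `correlation`, plus attribute `selected`
#'   (integer indices).
#' @export
screen_imfs <- function(decomp, x, threshold = 95, min_keep = 4) {
  if (decomp$n == 0) {
    rep <- data.frame(imf = integer(0), contribution_pct = numeric(0),
                      correlation = numeric(0))
    attr(rep, "selected") <- integer(0)
    class(rep) <- c("imf_screen_report", "data.frame")
    return(rep)
  }
  v <- vapply(decomp$imfs, stats::var, numeric(1))
  contrib <- 100 * v / sum(v)
  cors <- vapply(decomp$imfs, function(ci)
    if (stats::sd(ci) == 0) 0 else stats::cor(ci, x), numeric(1))
  sel_n <- which(cumsum(contrib) >= threshold)[1]
  if (is.na(sel_n)) sel_n <- decomp$n
  sel_n <- min(max(sel_n, min_keep), decomp$n)
  rep <- data.frame(imf = seq_len(decomp$n), contribution_pct = contrib,
                    correlation = cors)
  attr(rep, "selected") <- seq_len(sel_n)
  class(rep) <- c("imf_screen_report", "data.frame")
  rep
}

#' Hybrid EMD+AR feature vector for one trial
#'
#' Per channel: EMD-decompose, keep (or zero-pad to) `k_imfs` IMFs,
#' energy-normalise each, fit a least-squares AR model of order `m` (or a
#' per-IMF FPE-selected order capped at `m_max` when `m = "fpe"`), and
#' concatenate per-IMF blocks `[h_1..h_m, e2]` across IMFs then channels.
#' The h-coordinates are invariant to positive rescaling of the trial.
#'
#' @param trial Channel x sample matrix with channel rownames.
#' @param channels Channels used (default FP2 and F8).
#' @param k_imfs IMF slots per channel.
#' @param m AR order per IMF, or `"fpe"`.
#' @param m_max Order cap when `m = "fpe"`.
#' @param cfg A [sift_config()].
#' @param decomps Optional pre-computed decompositions named by channel.
#' @return Named numeric vector of length
#'   `length(channels) * k_imfs * (m + 1)` (fixed `m`).
#' @export
emdar_features <- function(trial, channels = c("FP2", "F8"), k_imfs = 4,
                           m = 4, m_max = 8, cfg = sift_config(),
                           decomps = NULL) {
  missing_ch <- setdiff(channels, rownames(trial))
  if (length(missing_ch))
    stop("emdar_features: missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  use_fpe <- identical(m, "fpe")
  out <- numeric(0)
  nms <- character(0)
  for (ch in channels) {
    d <- if (!is.null(decomps)) decomps[[ch]]
         else emd_decompose(trial[ch, ], cfg)
    dt <- 1                                    # unit-spacing energy convention
    for (j in seq_len(k_imfs)) {
      ci <- if (j <= d$n) d$imfs[[j]] else numeric(d$input_length)
      cbar <- energy_normalize(ci, dt)
      mj <- if (use_fpe && !all(cbar == 0)) fpe_order(cbar, m_max) else
        if (use_fpe) m_max else m
      fit <- ls_ar_fit(cbar, if (use_fpe) m_max else m)
      # with "fpe", fit at m_max but zero out coefficients beyond mj so the
      # feature matrix stays rectangular
      h <- fit$h
      if (use_fpe && mj < length(h)) {
        fit2 <- ls_ar_fit(cbar, mj)
        h <- c(fit2$h, numeric(length(h) - mj))
        fit$e2 <- fit2$e2
      }
      out <- c(out, h, fit$e2)
      nms <- c(nms, paste0(ch, "_IMF", j, "_h", seq_along(h)),
               paste0(ch, "_IMF", j, "_e2"))
    }
  }
  names(out) <- nms
  out
}

#' Class-template eigenvectors
#'
#' Column means of the feature matrix within each class: the per-class
#' average of every AR parameter and residual variance.
#'
#' @param features Numeric matrix, trials x features (named columns).
#' @param labels Per-trial class labels.
#' @return Matrix with one row per class, rownames `static` / `moving`.
#' @export
class_templates <- function(features, labels) {
  classes <- c("static", "moving")
  miss <- classes[!classes %in% labels]
  if (length(miss))
    stop("class_templates: no samples for class ", paste(miss, collapse = ", "))
  t(sapply(classes, function(cl)
    colMeans(features[labels == cl, , drop = FALSE])))
}
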