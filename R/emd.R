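#' Sifting configuration for empirical mode decomposition
#'
#' Bundles the tunable parameters of the sifting loop. The IMF admissibility
#' test (extrema/zero-crossing balance plus a locally symmetric envelope
#' midline) and the Cauchy-type standard-deviation criterion are combined:
#' sifting of one mode stops as soon as either triggers, or after `max_sifts`
#' iterations.
#'
#' @param sd_threshold Cauchy stopping threshold on
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` between successive sifts.
#' @param max_sifts Hard cap on sifting iterations per IMF.
#' @param max_imfs Hard cap on the number of extracted IMFs; hitting it
#'   raises a warning (it usually signals over-decomposition of noise).
#' @param boundary Envelope boundary policy; only `"mirror"` (reflection of
#'   the two nearest extrema about each end point) is implemented.
#' @param extrema_tol Absolute tolerance under which successive samples are
#'   treated as a plateau; a plateau contributes one extremum at its midpoint.
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sifts = 100L, max_imfs = 12L,
                        boundary = "mirror", extrema_tol = 0) {
  stopifnot(sd_threshold > 0, max_sifts >= 1, max_imfs >= 1)
  boundary <- match.arg(boundary, "mirror")
  structure(list(sd_threshold = sd_threshold, max_sifts = as.integer(max_sifts),
                 max_imfs = as.integer(max_imfs), boundary = boundary,
                 extrema_tol = extrema_tol),
            class = "sift_config")
}

#' Locate strict local extrema with plateau handling
#'
#' Successive samples whose difference is within `extrema_tol` form a plateau;
#' a plateau bounded by a rise and a fall (or fall and rise) is reported once,
#' at its midpoint. Monotone stretches contribute nothing.
#'
#' @param x Numeric vector, length >= 3.
#' @param extrema_tol Plateau tolerance on successive differences.
#' @return A list with integer vectors `max_idx`, `min_idx` (strictly
#'   increasing, 1-based) and numeric `max_val`, `min_val`.
#' @export
find_extrema <- function(x, extrema_tol = 0) {
  n <- length(x)
  if (n < 3) stop("find_extrema: input must have length >= 3")
  d <- diff(x)
  s <- sign(d)
  s[abs(d) <= extrema_tol] <- 0
  ii <- which(s != 0)
  if (length(ii) < 2) {
    return(list(max_idx = integer(0), max_val = numeric(0),
                min_idx = integer(0), min_val = numeric(0)))
  }
  ss <- s[ii]
  chg <- which(ss[-length(ss)] != ss[-1])
  # slope + -> - is a maximum; the extremum sits midway across any plateau
  # between difference indices ii[k] and ii[k+1]
  mid <- (ii[chg] + ii[chg + 1L]) %/% 2L + 1L
  is_max <- ss[chg] > 0
  max_idx <- mid[is_max]
  min_idx <- mid[!is_max]
  list(max_idx = max_idx, max_val = x[max_idx],
       min_idx = min_idx, min_val = x[min_idx])
}

# Mirror-extend extrema about the signal ends: the two extrema nearest each
# end are reflected outside the support so the spline is anchored beyond it.
mirror_extend <- function(idx, val, n) {
  k <- min(2L, length(idx))
  left_idx <- 2L - rev(idx[seq_len(k)])          # reflect about sample 1
  left_val <- rev(val[seq_len(k)])
  tail_sel <- seq.int(length(idx) - k + 1L, length(idx))
  right_idx <- 2L * n - rev(idx[tail_sel])       # reflect about sample n
  right_val <- rev(val[tail_sel])
  list(idx = c(left_idx, idx, right_idx), val = c(left_val, val, right_val))
}

#' Natural cubic-spline envelope through extrema
#'
#' Fits a natural cubic spline through the given extrema after mirror
#' extension at both ends, and evaluates it at every sample `1..length`.
#' The spline interpolates each interior extremum exactly.
#'
#' @param idx Integer extrema positions (1-based, strictly increasing).
#' @param val Extrema values.
#' @param length Number of samples to evaluate over.
#' @param boundary Boundary policy, `"mirror"`.
#' @return Numeric vector of length `length`.
#' @export
spline_envelope <- function(idx, val, length, boundary = "mirror") {
  if (base::length(idx) < 2)
    stop("spline_envelope: need at least 2 extrema")
  match.arg(boundary, "mirror")
  ext <- mirror_extend(idx, val, length)
  keep <- !duplicated(ext$idx)
  f <- stats::splinefun(ext$idx[keep], ext$val[keep], method = "natural")
  f(seq_len(length))
}

#' One sifting step
#'
#' Computes upper and lower cubic-spline envelopes of `h`, their pointwise
#' mean `m`, and returns `h - m` together with `m`.
#'
#' @param h Numeric vector with at least 2 maxima and 2 minima.
#' @param cfg A [sift_config()].
#' @return List with `h_next` and `m`, both the length of `h`.
#' @export
sift_once <- function(h, cfg = sift_config()) {
  n <- length(h)
  ex <- find_extrema(h, cfg$extrema_tol)
  if (length(ex$max_idx) < 2 || length(ex$min_idx) < 2)
    stop("sift_once: fewer than 2 maxima or minima")
  upper <- spline_envelope(ex$max_idx, ex$max_val, n, cfg$boundary)
  lower <- spline_envelope(ex$min_idx, ex$min_val, n, cfg$boundary)
  m <- (upper + lower) / 2
  list(h_next = h - m, m = m)
}

# zero crossings: sign changes between consecutive nonzero samples; a run of
# exact zeros counts once (it either carries the flip or is a touch)
count_zero_crossings <- function(x) {
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) < 2) return(sum(rle(s == 0)$values))
  sn <- s[nz]
  flips <- sum(sn[-length(sn)] != sn[-1])
  r <- rle(s == 0)
  touch_runs <- 0L
  pos <- cumsum(r$lengths)
  for (k in which(r$values)) {
    before <- if (k > 1) s[pos[k] - r$lengths[k]] else 0
    after <- if (k < length(r$values)) s[pos[k] + 1L] else 0
    if (before == after && before != 0) touch_runs <- touch_runs + 1L
  }
  flips + touch_runs
}

#' Test whether a sequence is an intrinsic mode function
#'
#' A sequence qualifies when (1) its numbers of extrema and zero crossings
#' differ by at most one, and (2) the mean absolute envelope midline over the
#' central 80% of samples is below 5% of its RMS. The absolute value matters:
#' a midline that oscillates but averages to zero (e.g. a strong
#' low-frequency rider under a fast carrier) is not locally symmetric about
#' the time axis.
#'
#' @param c Numeric vector.
#' @param extrema_tol Plateau tolerance, as in [find_extrema()].
#' @return Logical scalar with attribute `diagnostics` (a list with
#'   `n_extrema`, `n_zero_crossings`, `midline_ratio`).
#' @export
is_imf <- function(c, extrema_tol = 0) {
  n <- length(c)
  ex <- find_extrema(c, extrema_tol)
  n_ext <- length(ex$max_idx) + length(ex$min_idx)
  n_zc <- count_zero_crossings(c)
  diag_ <- list(n_extrema = n_ext, n_zero_crossings = n_zc,
                midline_ratio = NA_real_)
  ok_counts <- abs(n_ext - n_zc) <= 1
  ok_midline <- FALSE
  if (length(ex$max_idx) >= 2 && length(ex$min_idx) >= 2) {
    upper <- spline_envelope(ex$max_idx, ex$max_val, n)
    lower <- spline_envelope(ex$min_idx, ex$min_val, n)
    mid <- (upper + lower) / 2
    central <- central_window(n, 0.8)
    rms <- sqrt(mean(c^2))
    ratio <- if (rms > 0) mean(abs(mid[central])) / rms else 0
    diag_$midline_ratio <- ratio
    ok_midline <- ratio < 0.05
  }
  structure(ok_counts && ok_midline, diagnostics = diag_)
}

# indices of the central `fraction` of n samples (edge trimming)
central_window <- function(n, fraction = 0.8) {
  lo <- floor(n * (1 - fraction) / 2) + 1L
  hi <- n - floor(n * (1 - fraction) / 2)
  lo:hi
}

#' Extract one intrinsic mode function by repeated sifting
#'
#' Repeats [sift_once()] until the iterate passes [is_imf()], the Cauchy
#' criterion `sum((h_prev - h)^2)/sum(h_prev^2) < sd_threshold` fires, or
#' `max_sifts` is reached.
#'
#' @param x Numeric vector, not monotone.
#' @param cfg A [sift_config()].
#' @return List with `c` (the IMF) and `sift_count`.
#' @export
extract_imf <- function(x, cfg = sift_config()) {
  ex <- find_extrema(x, cfg$extrema_tol)
  if (length(ex$max_idx) < 2 || length(ex$min_idx) < 2)
    stop("extract_imf: input is monotone or has too few extrema")
  h <- x
  count <- 0L
  repeat {
    step <- sift_once(h, cfg)
    count <- count + 1L
    sd_crit <- sum((h - step$h_next)^2) / sum(h^2)
    h <- step$h_next
    if (count >= cfg$max_sifts) break
    if (sd_crit < cfg$sd_threshold) break
    if (isTRUE(as.logical(is_imf(h, cfg$extrema_tol)))) break
    # next round needs enough extrema; if sifting flattened the signal, stop
    exh <- find_extrema(h, cfg$extrema_tol)
    if (length(exh$max_idx) < 2 || length(exh$min_idx) < 2) break
  }
  list(c = h, sift_count = count)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions plus a residual by
#' iterating [extract_imf()] on successive residuals. Decomposition stops
#' when the residual is monotone, has fewer than 2 interior maxima or minima,
#' or `max_imfs` is reached. The components recombine exactly:
#' `x == rowSums(imfs) + residual` up to floating point.
#'
#' @param x Numeric vector, length >= 16, finite.
#' @param cfg A [sift_config()].
#' @return An object of class `imf_decomposition`: list with `imfs` (list of
#'   numeric vectors, highest frequency first), `residual`, `n`,
#'   `sift_counts`, `input_length`.
#' @export
emd_decompose <- function(x, cfg = sift_config()) {
  stopifnot(length(x) >= 16, all(is.finite(x)))
  imfs <- list()
  sift_counts <- integer(0)
  r <- x
  repeat {
    ex <- find_extrema(r, cfg$extrema_tol)
    if (length(ex$max_idx) < 2 || length(ex$min_idx) < 2) break
    if (length(imfs) >= cfg$max_imfs) {
      warning("emd_decompose: max_imfs reached; residual still oscillatory")
      break
    }
    res <- extract_imf(r, cfg)
    imfs[[length(imfs) + 1L]] <- res$c
    sift_counts <- c(sift_counts, res$sift_count)
    r <- r - res$c
  }
  structure(list(imfs = imfs, residual = r, n = length(imfs),
                 sift_counts = sift_counts, input_length = length(x)),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("IMF decomposition: %d IMFs + residual (%d samples)\n",
              x$n, x$input_length))
  if (x$n > 0) {
    v <- vapply(x$imfs, stats::var, numeric(1))
    cat("  variance contribution (%):",
        paste(sprintf("%.2f", 100 * v / sum(v)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Reconstruct the input from a decomposition
#'
#' @param decomp An `imf_decomposition`.
#' @return Numeric vector: sum of all IMFs plus the residual.
#' @export
emd_reconstruct <- function(decomp) {
  out <- decomp$residual
  for (c_j in decomp$imfs) out <- out + c_j
  out
}
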