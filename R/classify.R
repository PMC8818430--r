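#' Build a feature matrix for a trial set
#'
#' Applies one of the three extractors to every trial. EMD decompositions of
#' the requested channels are computed once per trial and shared between the
#' HHT and EMD+AR extractors when both are requested elsewhere (see
#' [run_pipeline()]); here `method` selects a single extractor.
#'
#' @param ts A preprocessed [trial_set()].
#' @param method `"hht"`, `"ar"` or `"emdar"`.
#' @param channels Channels used for features.
#' @param ... Passed to the extractor ([hht_features()], [ar_features()],
#'   [emdar_features()]).
#' @return List with `x` (trials x features matrix) and `labels`.
#' @export
feature_matrix <- function(ts, method = c("emdar", "hht", "ar"),
                           channels = c("FP2", "F8"), ...) {
  method <- match.arg(method)
  n <- dim(ts$trials)[1]
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    m <- trial_matrix(ts, k)
    rows[[k]] <- switch(method,
      hht = hht_features(m, channels = channels, ...),
      ar = ar_features(m, channels = channels, ...),
      emdar = emdar_features(m, channels = channels, ...))
  }
  x <- do.call(rbind, rows)
  list(x = x, labels = ts$labels, method = method)
}

median_heuristic_gamma <- function(x, max_points = 200) {
  n <- nrow(x)
  if (n > max_points) x <- x[seq(1, n, length.out = max_points), , drop = FALSE]
  d2 <- as.numeric(stats::dist(x))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 else 1 / med
}

#' Train and evaluate an SVM on a stratified split
#'
#' Splits each class into `n_train_per_class` / `n_test_per_class` trials at
#' random (by `seed`), z-scores every feature using training-set statistics
#' only, fits a support-vector machine, and reports test accuracy.
#'
#' @param features List as returned by [feature_matrix()] (`x`, `labels`),
#'   or a numeric matrix (then `labels` must be given).
#' @param n_train_per_class,n_test_per_class Split sizes per class.
#' @param kernel `"radial"` (inverse bandwidth from the median heuristic on
#'   the training set) or `"linear"`.
#' @param cost SVM regularisation constant.
#' @param seed Split seed.
#' @param labels Per-trial labels when `features` is a bare matrix.
#' @return An object of class `classification_result`: list with `accuracy`
#'   (percent), `per_class_accuracy`, `confusion`, `n_train`, `n_test`,
#'   `kernel`, `cost`, `gamma`, `seed`.
#' @export
train_eval <- function(features, n_train_per_class, n_test_per_class,
                       kernel = c("radial", "linear"), cost = 1, seed = 1L,
                       labels = NULL) {
  kernel <- match.arg(kernel)
  if (is.list(features) && !is.null(features$x)) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- features
  }
  stopifnot(!is.null(labels), nrow(x) == length(labels))
  classes <- c("static", "moving")
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  need <- n_train_per_class + n_test_per_class
  if (any(vapply(idx_by_class, length, integer(1)) < need))
    stop("train_eval: not enough trials per class for the requested split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_idx <- integer(0)
  test_idx <- integer(0)
  for (ii in idx_by_class) {
    sh <- sample(ii)
    train_idx <- c(train_idx, sh[seq_len(n_train_per_class)])
    test_idx <- c(test_idx,
                  sh[n_train_per_class + seq_len(n_test_per_class)])
  }
  xtr <- x[train_idx, , drop = FALSE]
  xte <- x[test_idx, , drop = FALSE]
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
  ytr <- factor(labels[train_idx], levels = classes)
  yte <- factor(labels[test_idx], levels = classes)
  gamma <- if (kernel == "radial") median_heuristic_gamma(xtr) else NA_real_
  fit <- if (kernel == "radial")
    e1071::svm(xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  else
    e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, xte)
  conf <- table(truth = yte, pred = pred)
  acc <- 100 * mean(pred == yte)
  per_class <- 100 * diag(prop.table(conf, 1))
  structure(list(accuracy = acc, per_class_accuracy = per_class,
                 confusion = conf,
                 n_train = length(train_idx), n_test = length(test_idx),
                 kernel = kernel, cost = cost, gamma = gamma,
                 seed = seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("SVM (%s, cost=%g): accuracy %.2f%% on %d test trials\n",
              x$kernel, x$cost, x$accuracy, x$n_test))
  invisible(x)
}

#' Summarise per-subject accuracies
#'
#' One row per feature method: mean accuracy with its standard error across
#' subjects, the grand maximum and grand minimum, plus a formatted
#' `mean_pm_se` column (e.g. `"68.14 ± 3.06"`).
#'
#' @param results Named list (one element per method) of numeric vectors of
#'   per-subject accuracies in percent.
#' @return Data frame with columns `method`, `average`, `se`, `maximum`,
#'   `minimum`, `mean_pm_se`.
#' @export
subject_summary <- function(results) {
  stopifnot(length(results) >= 1)
  rows <- lapply(names(results), function(meth) {
    a <- results[[meth]]
    se <- if (length(a) > 1) stats::sd(a) / sqrt(length(a)) else 0
    data.frame(method = meth, average = mean(a), se = se,
               maximum = max(a), minimum = min(a),
               mean_pm_se = sprintf("%.2f ± %.2f", mean(a), se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time-resolved classification accuracy
#'
#' Slides a window over the epoch; within each window, features are
#' re-extracted from the windowed samples and [train_eval()] is run with the
#' same split seed, giving one accuracy per window end time.
#'
#' @param ts A preprocessed [trial_set()].
#' @param method Feature method, as in [feature_matrix()].
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param n_train_per_class,n_test_per_class Split sizes.
#' @param seed Split seed.
#' @param ... Passed to the feature extractor.
#' @return An object of class `accuracy_curve`: data frame with
#'   `window_end_s` and `accuracy_pct`.
#' @export
time_resolved_accuracy <- function(ts, method = "ar", window_s = 1,
                                   step_s = 0.5, n_train_per_class,
                                   n_test_per_class, seed = 1L, ...) {
  epoch_s <- diff(ts$window)
  stopifnot(window_s <= epoch_s, step_s > 0)
  n_win_samp <- round(window_s * ts$fs)
  if (method == "ar" && n_win_samp <= 3 * 6)
    stop("time_resolved_accuracy: window too short for the AR order")
  starts <- seq(0, epoch_s - window_s + 1e-9, by = step_s)
  out <- data.frame(window_end_s = starts + window_s,
                    accuracy_pct = NA_real_)
  for (w in seq_along(starts)) {
    i0 <- round(starts[w] * ts$fs) + 1L
    sub <- ts
    sub$trials <- ts$trials[, , i0:(i0 + n_win_samp - 1L), drop = FALSE]
    sub$window <- c(0, window_s)
    fm <- feature_matrix(sub, method, ...)
    res <- train_eval(fm, n_train_per_class, n_test_per_class, seed = seed)
    out$accuracy_pct[w] <- res$accuracy
  }
  class(out) <- c("accuracy_curve", "data.frame")
  out
}
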