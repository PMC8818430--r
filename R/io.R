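#' Write a trial set to delimited files
#'
#' One CSV per trial (sample rows x channel columns, header of channel
#' labels), a `labels.csv` (`trial_id`, `class`), and a JSON sidecar with
#' the generating configuration when present.
#'
#' @param ts A [trial_set()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_trialset <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ts$trials)[1]
  for (k in seq_len(n)) {
    m <- t(trial_matrix(ts, k))                 # sample rows x channel cols
    utils::write.csv(as.data.frame(m),
                     file.path(dir, sprintf("trial_%04d.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(trial_id = seq_len(n), class = ts$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- list(fs = ts$fs, channel_labels = ts$channel_labels,
               window = ts$window)
  if (!is.null(ts$config)) meta$config <- unclass(ts$config)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial set written by [write_trialset()]
#'
#' @param dir Directory containing `trial_*.csv`, `labels.csv`,
#'   `dataset.json`.
#' @return A [trial_set()].
#' @export
read_trialset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  files <- sprintf("trial_%04d.csv", lab$trial_id)
  first <- as.matrix(utils::read.csv(file.path(dir, files[1])))
  trials <- array(0, dim = c(nrow(lab), ncol(first), nrow(first)))
  for (k in seq_len(nrow(lab))) {
    m <- as.matrix(utils::read.csv(file.path(dir, files[k])))
    trials[k, , ] <- t(m)
  }
  trial_set(trials, lab$class, meta$fs, meta$channel_labels,
            window = meta$window)
}

#' Write an IMF decomposition to a delimited file
#'
#' Columns `IMF1..IMFn` plus `residual`; a JSON sidecar (`<path>.json`)
#' records the number of IMFs and per-IMF sift counts.
#'
#' @param decomp An `imf_decomposition`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_imf_decomposition <- function(decomp, path) {
  m <- do.call(cbind, c(decomp$imfs, list(decomp$residual)))
  colnames(m) <- c(paste0("IMF", seq_len(decomp$n)), "residual")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  jsonlite::write_json(list(n = decomp$n, sift_counts = decomp$sift_counts,
                            input_length = decomp$input_length),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an IMF decomposition written by [write_imf_decomposition()]
#'
#' @param path CSV path.
#' @return An `imf_decomposition`.
#' @export
read_imf_decomposition <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- ncol(m) - 1L
  structure(list(imfs = lapply(seq_len(n), function(j) unname(m[, j])),
                 residual = unname(m[, n + 1L]), n = n,
                 sift_counts = meta$sift_counts,
                 input_length = meta$input_length),
            class = "imf_decomposition")
}
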