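#' Evaluate all feature methods on one synthetic subject
#'
#' Generates one synthetic dataset (the "subject" is the dataset seed),
#' preprocesses it, extracts features by each requested method — EMD
#' decompositions of the feature channels are computed once per trial and
#' shared between the HHT and EMD+AR extractors — and evaluates each with
#' [train_eval()].
#'
#' @param subject_seed Dataset seed for [synth_config()].
#' @param methods Subset of `c("hht", "ar", "emdar")`.
#' @param synth_args Named list of overrides for [synth_config()].
#' @param n_train_per_class,n_test_per_class Split sizes (defaults: half of
#'   each class trains, half tests — 100 train / 100 test at the default
#'   100 trials per class).
#' @param channels Feature channels.
#' @param split_seed Seed for the train/test split.
#' @param ... Passed to [train_eval()] (kernel, cost).
#' @return Named list of `classification_result`s, one per method.
#' @export
run_subject <- function(subject_seed, methods = c("hht", "ar", "emdar"),
                        synth_args = list(),
                        n_train_per_class = NULL, n_test_per_class = NULL,
                        channels = c("FP2", "F8"), split_seed = NULL, ...) {
  methods <- match.arg(methods, c("hht", "ar", "emdar"), several.ok = TRUE)
  cfg <- do.call(synth_config, c(synth_args, list(seed = subject_seed)))
  ds <- generate_dataset(cfg)
  # only the feature channels are carried through preprocessing and EMD
  keep <- match(channels, ds$channel_labels)
  if (anyNA(keep)) stop("run_subject: channels not present in dataset")
  ds$trials <- ds$trials[, keep, , drop = FALSE]
  ds$channel_labels <- channels
  pp <- preprocess_trialset(ds, path = "bandpass")
  if (is.null(n_train_per_class))
    n_train_per_class <- cfg$n_trials_per_class %/% 2
  if (is.null(n_test_per_class))
    n_test_per_class <- cfg$n_trials_per_class - n_train_per_class
  if (is.null(split_seed)) split_seed <- trial_seed(subject_seed, 999983L)
  n <- dim(pp$trials)[1]
  need_emd <- any(c("hht", "emdar") %in% methods)
  decomps <- NULL
  if (need_emd) {
    decomps <- vector("list", n)
    for (k in seq_len(n)) {
      m <- trial_matrix(pp, k)
      decomps[[k]] <- stats::setNames(
        lapply(channels, function(ch) emd_decompose(m[ch, ])), channels)
    }
  }
  out <- list()
  for (meth in methods) {
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      m <- trial_matrix(pp, k)
      rows[[k]] <- switch(meth,
        hht = hht_features(m, channels = channels, decomps = decomps[[k]]),
        ar = ar_features(m, channels = channels),
        emdar = emdar_features(m, channels = channels,
                               decomps = decomps[[k]]))
    }
    fm <- list(x = do.call(rbind, rows), labels = pp$labels)
    out[[meth]] <- train_eval(fm, n_train_per_class, n_test_per_class,
                              seed = split_seed, ...)
  }
  out
}

#' Multi-subject experiment
#'
#' Runs [run_subject()] for `n_subjects` independent dataset seeds (derived
#' from `base_seed`) and summarises per-method accuracies with
#' [subject_summary()].
#'
#' @param n_subjects Number of synthetic subjects.
#' @param base_seed Seed from which per-subject seeds are derived.
#' @param methods Feature methods to compare.
#' @param synth_args Overrides for [synth_config()].
#' @param ... Passed to [run_subject()].
#' @return List with `per_subject` (methods x subjects matrix of accuracies)
#'   and `summary` (data frame from [subject_summary()]).
#' @export
run_experiment <- function(n_subjects = 18, base_seed = 1L,
                           methods = c("hht", "ar", "emdar"),
                           synth_args = list(), ...) {
  seeds <- vapply(seq_len(n_subjects),
                  function(s) trial_seed(base_seed, 424243L + s), integer(1))
  acc <- matrix(NA_real_, length(methods), n_subjects,
                dimnames = list(methods, paste0("subject", seq_len(n_subjects))))
  for (s in seq_len(n_subjects)) {
    res <- run_subject(seeds[s], methods = methods, synth_args = synth_args,
                       ...)
    for (meth in methods) acc[meth, s] <- res[[meth]]$accuracy
  }
  per_method <- stats::setNames(lapply(methods, function(m) acc[m, ]), methods)
  list(per_subject = acc, summary = subject_summary(per_method))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates synth -> preprocess -> features -> classification ->
#' band statistics, and writes a report directory: a per-subject accuracy
#' table, a method summary table, the band-statistics grid, and a JSON
#' manifest with the full configuration and its hash. Rerunning with the
#' same configuration reproduces every output.
#'
#' @param config Nested named list (or path to a YAML file) with optional
#'   entries `seed`, `n_subjects`, `methods`, `synth` (overrides for
#'   [synth_config()]), `svm` (`kernel`, `cost`), `bandstats` (logical
#'   toggle), `out_dir`. Unknown top-level keys are an error.
#' @return Invisibly, a list with the experiment results, the band
#'   statistics (or `NULL`) and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "n_subjects", "methods", "synth", "svm", "bandstats",
             "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("run_pipeline: unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  n_subjects <- config$n_subjects %||% 18L
  methods <- config$methods %||% c("hht", "ar", "emdar")
  synth_args <- config$synth %||% list()
  svm_args <- config$svm %||% list()
  exp <- do.call(run_experiment,
                 c(list(n_subjects = n_subjects, base_seed = seed,
                        methods = methods, synth_args = synth_args),
                   svm_args))
  bs <- NULL
  if (isTRUE(config$bandstats)) {
    cfg <- do.call(synth_config,
                   c(synth_args, list(seed = trial_seed(seed, 777773L))))
    ds <- generate_dataset(cfg)
    pp <- preprocess_trialset(ds, path = "notch")
    bs <- band_stats_table(pp)
  }
  manifest <- list(
    package = "viemdar",
    config = config,
    config_hash = config_hash(config),
    r_version = as.character(getRversion()))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(t(exp$per_subject)),
                     file.path(config$out_dir, "per_subject_accuracy.csv"))
    utils::write.csv(exp$summary,
                     file.path(config$out_dir, "method_summary.csv"),
                     row.names = FALSE)
    if (!is.null(bs))
      utils::write.csv(as.data.frame(bs$ttest),
                       file.path(config$out_dir, "band_ttest_p.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(experiment = exp, bandstats = bs, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-independent hash of the configuration list (no external digest
# dependency: serialize canonically and fold into hex)
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  s <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- c(17L, 31L, 73L, 127L)
  for (i in seq_along(bytes))
    h[(i %% 4) + 1L] <- (h[(i %% 4) + 1L] * 131L + bytes[i]) %% 1048573L
  paste(sprintf("%05x", h), collapse = "")
}
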