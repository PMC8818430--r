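make_clouds <- function(n_per_class, centre = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * 4, -centre), ncol = 4),
             matrix(stats::rnorm(n_per_class * 4, centre), ncol = 4))
  colnames(x) <- paste0("f", 1:4)
  list(x = x, labels = rep(c("static", "moving"), each = n_per_class))
}

test_that("separable clouds classify nearly perfectly", {
  cl <- make_clouds(100)
  res <- train_eval(cl$x, 50, 50, seed = 7, labels = cl$labels)
  expect_gte(res$accuracy, 95)
  expect_equal(res$n_train, 100)
  expect_equal(res$n_test, 100)
  expect_equal(sum(res$confusion), res$n_test)
  expect_equal(res$kernel, "radial")
})

test_that("permuted labels give chance accuracy", {
  cl <- make_clouds(100)
  set.seed(11)
  shuffled <- sample(cl$labels)
  res <- train_eval(cl$x, 50, 50, seed = 7, labels = shuffled)
  half <- 100 * c(0.5 - 2.576 * sqrt(0.25 / 100),
                  0.5 + 2.576 * sqrt(0.25 / 100))
  expect_gte(res$accuracy, half[1])
  expect_lte(res$accuracy, half[2])
})

test_that("evaluation is deterministic and validates the split", {
  cl <- make_clouds(30)
  r1 <- train_eval(cl$x, 15, 15, seed = 3, labels = cl$labels)
  r2 <- train_eval(cl$x, 15, 15, seed = 3, labels = cl$labels)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$gamma, r2$gamma)

  expect_error(train_eval(cl$x, 25, 25, seed = 1, labels = cl$labels),
               "not enough trials")
})

test_that("linear kernel is available and recorded", {
  cl <- make_clouds(40)
  res <- train_eval(cl$x, 20, 20, kernel = "linear", seed = 5,
                    labels = cl$labels)
  expect_equal(res$kernel, "linear")
  expect_gte(res$accuracy, 95)
})

test_that("subject summaries aggregate and format as expected", {
  s1 <- subject_summary(list(emdar = 70))
  expect_equal(s1$average, 70)
  expect_equal(s1$maximum, 70)
  expect_equal(s1$minimum, 70)

  s2 <- subject_summary(list(hht = c(60, 80)))
  expect_equal(s2$average, 70)
  expect_equal(s2$maximum, 80)
  expect_equal(s2$minimum, 60)
  expect_match(s2$mean_pm_se, "^70\\.00 ± 10\\.00$")
})

test_that("time-resolved accuracy localises a late-epoch effect", {
  # two classes identical early, different 10 Hz amplitude late
  fs <- 250
  n_per <- 24
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  late <- t >= 2
  set.seed(19)
  trials <- array(0, dim = c(2 * n_per, 2, length(t)))
  labels <- rep(c("static", "moving"), each = n_per)
  for (k in seq_len(2 * n_per)) {
    for (ch in 1:2) {
      amp <- ifelse(rep(labels[k] == "moving", length(t)) & late, 4, 1)
      trials[k, ch, ] <- amp * sin(2 * pi * 10 * t + stats::runif(1, 0, 6)) +
        stats::rnorm(length(t), sd = 1)
    }
  }
  ts <- trial_set(trials, labels, fs, c("FP2", "F8"))
  curve <- time_resolved_accuracy(ts, method = "hht", window_s = 1,
                                  step_s = 1, n_train_per_class = 12,
                                  n_test_per_class = 12, seed = 2)
  expect_equal(nrow(curve), floor((4 - 1) / 1) + 1)
  expect_true(all(diff(curve$window_end_s) > 0))
  early <- curve$accuracy_pct[curve$window_end_s <= 2]
  late_acc <- curve$accuracy_pct[curve$window_end_s > 2]
  expect_gt(mean(late_acc), mean(early))

  expect_error(time_resolved_accuracy(ts, method = "ar", window_s = 0.05,
                                      step_s = 1, n_train_per_class = 12,
                                      n_test_per_class = 12),
               "window too short")
})
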