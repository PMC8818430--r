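test_that("energy normalisation yields unit energy and scale invariance", {
  set.seed(31)
  c1 <- stats::rnorm(500)
  n1 <- energy_normalize(c1)
  expect_lt(abs(sum(n1^2) - 1), 1e-9)
  expect_equal(energy_normalize(n1), n1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(energy_normalize(7 * c1), n1, ignore_attr = TRUE)

  z <- energy_normalize(numeric(100))
  expect_true(all(z == 0))
  expect_true(attr(z, "zero_padded"))
})

test_that("IMF-count padding aligns decompositions without reordering", {
  fake <- function(n_imfs, len = 64) {
    structure(list(imfs = lapply(seq_len(n_imfs), function(j) rep(j, len)),
                   residual = numeric(len), n = as.integer(n_imfs),
                   sift_counts = rep(1L, n_imfs), input_length = len),
              class = "imf_decomposition")
  }
  padded <- pad_imf_count(list(fake(6), fake(8), fake(7)))
  expect_equal(sapply(padded, function(d) as.integer(d$n)), c(8L, 8L, 8L))
  expect_true(all(padded[[1]]$imfs[[7]] == 0))
  expect_true(all(padded[[1]]$imfs[[8]] == 0))
  expect_equal(padded[[1]]$imfs[[6]], rep(6, 64))   # genuine IMFs preserved

  same <- pad_imf_count(list(fake(5), fake(5)))
  expect_equal(same[[1]]$imfs, fake(5)$imfs)
  single <- pad_imf_count(list(fake(3)))
  expect_equal(single[[1]]$n, 3L)
})

test_that("least-squares fits honour the sign convention and zero rule", {
  # c(t) = 0.5 c(t-1) + e  <=>  h1 = -0.5
  x <- sim_ar(0.5, 10000, sd = 1, seed = 41)
  fit <- ls_ar_fit(x, 1)
  expect_lt(abs(fit$h - (-0.5)), 0.03)
  expect_lt(abs(fit$e2 - 1) / 1, 0.05)

  zf <- ls_ar_fit(numeric(100), 4)
  expect_equal(zf$h, numeric(4))
  expect_equal(zf$e2, 0)
  expect_true(zf$zero_padded)

  expect_error(ls_ar_fit(rep(2, 100), 2), "singular")

  # least squares and Burg agree on a long AR(2) realisation
  x2 <- sim_ar(c(1.5, -0.75), 20000, seed = 42)
  expect_lt(max(abs(-ls_ar_fit(x2, 2)$h - burg_fit(x2, 2)$coeffs)), 0.02)
})

test_that("FPE selects the generating order modally", {
  picks <- vapply(1:20, function(s)
    fpe_order(sim_ar(c(1.5, -0.75), 4000, seed = 400 + s), m_max = 8),
    numeric(1))
  expect_equal(as.integer(names(which.max(table(picks)))), 2)

  noise_picks <- vapply(1:20, function(s) {
    set.seed(500 + s)
    fpe_order(stats::rnorm(2000), m_max = 8)
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(noise_picks)))), 1)

  expect_equal(fpe_order(sim_ar(0.5, 1000, seed = 1), m_max = 1), 1)
})

test_that("variance screening reports sensible contributions", {
  tt <- two_tone(a_hi = 2, a_lo = 1)
  x <- tt$hi + tt$lo
  d <- emd_decompose(x)
  rep <- screen_imfs(d, x)
  expect_lt(abs(rep$contribution_pct[1] - 80), 5)
  expect_lt(abs(rep$contribution_pct[2] - 20), 5)
  expect_lt(abs(sum(rep$contribution_pct) - 100), 0.01)
  expect_true(all(rep$correlation >= -1 & rep$correlation <= 1))
  expect_gte(length(attr(rep, "selected")), min(4, d$n))

  single <- structure(list(imfs = list(tt$hi), residual = tt$lo,
                           n = 1L, sift_counts = 1L, input_length = 4000),
                      class = "imf_decomposition")
  expect_equal(screen_imfs(single, x)$contribution_pct, 100)

  none <- emd_decompose(rep(1, 100))
  expect_equal(nrow(screen_imfs(none, rep(1, 100))), 0)
})

test_that("hybrid features have stable dimension, names and values", {
  pp <- synth_preprocessed()
  m <- viemdar:::trial_matrix(pp, 1)
  f <- emdar_features(m, k_imfs = 4, m = 4)
  expect_length(f, 2 * 4 * 5)
  expect_true(all(grepl("^(FP2|F8)_IMF[1-4]_(h[1-4]|e2)$", names(f))))
  expect_identical(f, emdar_features(m, k_imfs = 4, m = 4))

  z <- matrix(0, 2, 4000, dimnames = list(c("FP2", "F8"), NULL))
  expect_true(all(emdar_features(z) == 0))
})

test_that("hybrid h-features are invariant to positive rescaling", {
  pp <- synth_preprocessed()
  m <- viemdar:::trial_matrix(pp, 2)
  f1 <- emdar_features(m)
  f2 <- emdar_features(3.7 * m)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("class templates average features within classes", {
  x <- rbind(c(1, 2), c(3, 4), c(10, 20), c(10, 20))
  colnames(x) <- c("a", "b")
  tpl <- class_templates(x, c("static", "static", "moving", "moving"))
  expect_equal(unname(tpl["static", ]), c(2, 3))
  expect_equal(unname(tpl["moving", ]), c(10, 20))

  expect_error(class_templates(x[1:2, ], c("static", "static")),
               "moving")

  # identical samples give a template equal to either sample
  tpl2 <- class_templates(rbind(c(5, 6), c(5, 6), c(0, 0)),
                          c("moving", "moving", "static"))
  expect_equal(unname(tpl2["moving", ]), c(5, 6))
})

test_that("frontal templates separate classes at high contrast", {
  pp <- synth_preprocessed(n_per_class = 15, seed = 77, alpha_contrast = 2)
  fm <- feature_matrix(pp, "emdar")
  tpl <- class_templates(fm$x, fm$labels)
  pooled_se <- function(j) {
    a <- fm$x[fm$labels == "static", j]
    b <- fm$x[fm$labels == "moving", j]
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  fp2 <- grep("^FP2", colnames(fm$x))
  gaps <- vapply(fp2, function(j) {
    se <- pooled_se(j)
    if (se == 0) 0 else abs(tpl["static", j] - tpl["moving", j]) / se
  }, numeric(1))
  expect_gt(max(gaps), 2)
})

test_that("the literal energy-division variant scales as documented", {
  c1 <- tone(10, dur = 1)
  e <- sum(c1^2)
  expect_equal(energy_normalize(c1, literal = TRUE), c1 / e)
  expect_equal(energy_normalize(c1), c1 / sqrt(e))
})
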