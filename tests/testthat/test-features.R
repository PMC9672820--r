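test_that("energy is the sum of squared samples", {
  expect_identical(energy(c(1, 2, 2)), 9)
  expect_identical(energy(numeric(5)), 0)
  expect_equal(energy(tone(1, 10, 250, 1000)), 500, tolerance = 0.01)
})

test_that("morphological features match their direct formulas", {
  m <- morphological(c(1, -2, 3))
  expect_equal(unname(m), c(3, 4, -2, 2, 6))
  pos <- c(0.5, 2, 1)
  mp <- morphological(pos)
  expect_identical(unname(mp[c("na")]), 0)
  expect_equal(unname(mp["pa"]), sum(pos))
  expect_equal(unname(mp["tt"]), unname(mp["taa"]))
})

test_that("sign flip swaps positive and negative areas", {
  set.seed(31)
  x <- rnorm(100)
  m1 <- morphological(x)
  m2 <- morphological(-x)
  expect_equal(unname(m1["pa"]), unname(-m2["na"]))
  expect_equal(unname(m1["aa"]), unname(m2["aa"]))
  expect_equal(unname(m1["taa"]), unname(m2["taa"]))
})

test_that("total areas reduce to sum(x) and sum(|x|) algebraically", {
  set.seed(32)
  for (rep in 1:10) {
    x <- rnorm(50)
    m <- morphological(x)
    expect_identical(unname(m["tt"]), unname(m["pa"] + m["na"]))
    expect_identical(unname(m["taa"]), unname(m["pa"] + abs(m["na"])))
    expect_equal(unname(m["tt"]), sum(x), tolerance = 1e-12)
    expect_equal(unname(m["taa"]), sum(abs(x)), tolerance = 1e-12)
  }
  expect_equal(unname(morphological(c(1, -2, 3), aa_as_area = TRUE)["aa"]), 6)
})

test_that("fuzzy entropy matches the brute-force double-loop oracle", {
  set.seed(33)
  signals <- list(
    rnorm(12), rnorm(60), tone(1, 10, 100, 80) + rnorm(80, sd = 0.1),
    as.numeric(gen_signal(list(comp_ar_noise(0.7, 1)), 150, 100, seed = 2))
  )
  for (x in signals) {
    for (m in c(2, 3)) {
      r_abs <- 0.2 * sd(x)
      expect_equal(fuzzy_approx_entropy(x, m = m, r = 0.2, n_grad = 2),
                   fuzzyen_bruteforce(x, m, r_abs, 2), tolerance = 1e-12)
    }
  }
})

test_that("fuzzy entropy is exactly zero for a constant signal", {
  expect_identical(fuzzy_approx_entropy(rep(3.2, 50)), 0)
})

test_that("white noise is less regular than a same-variance tone", {
  for (s in 1:20) {
    set.seed(s)
    x_noise <- rnorm(300)
    x_tone <- tone(sqrt(2), 10, 250, 300)  # unit variance
    expect_gt(fuzzy_approx_entropy(x_noise), fuzzy_approx_entropy(x_tone))
  }
})

test_that("fuzzy entropy rejects invalid parameters", {
  expect_error(fuzzy_approx_entropy(rnorm(50), r = 0),
               class = "memdbci_invalid_spec")
  expect_error(fuzzy_approx_entropy(rnorm(3), m = 2),
               class = "memdbci_too_short")
})

test_that("the AR extractor returns the stated order with Burg estimates", {
  set.seed(34)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.75, -0.5)), 5000))
  fit <- ar_coefficients(x)
  expect_length(fit$coeffs, 7)
  fit2 <- ar_coefficients(x, order = 2)
  expect_equal(fit2$coeffs, c(0.75, -0.5), tolerance = 0.05)
  expect_gt(fit2$noise_variance, 0)
})

test_that("the AR sign convention reproduces the generating recursion", {
  # simulate x(t) = 0.9 x(t-1) + e(t); the fitted a(1) must be near +0.9
  set.seed(35)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  expect_equal(ar_coefficients(x, order = 1)$coeffs, 0.9, tolerance = 0.05)
})

test_that("white noise yields near-zero AR coefficients", {
  set.seed(36)
  fit <- ar_coefficients(rnorm(20000), order = 7)
  expect_true(all(abs(fit$coeffs) < 0.05))
})

test_that("degenerate AR inputs are rejected", {
  expect_error(ar_coefficients(rnorm(10), order = 7),
               class = "memdbci_too_short")
  expect_error(ar_coefficients(rep(1, 100)),
               class = "memdbci_degenerate_range")
})

test_that("the feature vector has the documented fixed layout", {
  tr <- gen_mi_trials(1, 2, n_channels = 1, duration = 1, seed = 41)
  fv <- extract_features(tr$trials[[1]], fs = tr$fs)
  expect_length(fv, 3 * (1 + 5 + 1 + 7))
  expect_identical(names(fv)[1:3], c("ch1_imf1_energy", "ch1_imf1_aa",
                                     "ch1_imf1_pa"))
  expect_identical(names(fv)[42], "ch1_imf3_ar7")
  fv2 <- extract_features(tr$trials[[1]], fs = tr$fs)
  expect_identical(fv, fv2)
  # two channels double the layout
  tr2 <- gen_mi_trials(1, 2, n_channels = 2, duration = 1, seed = 41)
  expect_length(extract_features(tr2$trials[[1]], fs = tr2$fs), 84)
})

test_that("missing IMFs zero-pad their feature slots", {
  x <- tone(1, 10, 250, 500)
  k <- ncol(emd_decompose(x, 250, max_imfs = 20)$imfs)
  fv <- extract_features(x, fs = 250,
                         cfg = feature_config(n_imfs = k + 2, method = "emd"))
  pad <- fv[grepl(paste0("imf", k + 1, "_|imf", k + 2, "_"), names(fv))]
  expect_length(pad, 2L * 14L)
  expect_identical(unname(pad), numeric(length(pad)))
})

test_that("a strong class effect separates mu-band IMF energies", {
  eff <- tibble::tibble(class = 0:1, mu_amp = c(2, 0.5),
                        beta_amp = c(1, 1))
  ts <- gen_mi_trials(8, 2, n_channels = 1, duration = 2,
                      class_effect = eff, noise_sd = 0.2, seed = 44)
  ft <- extract_feature_table(ts)
  en_cols <- grep("_energy$", names(ft), value = TRUE)
  sep <- vapply(en_cols, function(cl) {
    a <- ft[[cl]][ft$label == 0]
    b <- ft[[cl]][ft$label == 1]
    abs(mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
  }, numeric(1))
  expect_gt(max(sep), 3)
})

test_that("the feature table binds trials with ids and labels", {
  ts <- gen_mi_trials(2, 2, n_channels = 1, duration = 1, seed = 45)
  ft <- extract_feature_table(ts, cfg = feature_config(n_imfs = 2))
  expect_s3_class(ft, "tbl_df")
  expect_identical(dim(ft), c(4L, 2L + 2L * 14L))
  expect_identical(names(ft)[1], "trial_id")
  expect_identical(names(ft)[ncol(ft)], "label")
  expect_identical(ft$label, ts$labels)
})
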