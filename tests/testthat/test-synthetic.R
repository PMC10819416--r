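test_that("null generator and determinism", {
  null_spec <- fatigue_class_spec(0, list(delta = 0, theta = 0, alpha = 0, beta = 0),
                                  noise_floor = 0)
  expect_equal(generate_window(null_spec, 3, 100, 250, seed = 1),
               matrix(0, 3, 100))
  sp <- default_fatigue_classes()[[4]]
  expect_identical(generate_window(sp, 4, 500, 250, seed = 7),
                   generate_window(sp, 4, 500, 250, seed = 7))
  expect_false(identical(generate_window(sp, 4, 500, 250, seed = 7),
                         generate_window(sp, 4, 500, 250, seed = 8)))
  expect_error(generate_window(sp, 0, 100, 250), "dimensions")
  expect_error(generate_window(sp, 2, 1, 250), "dimensions")
})

test_that("default class gradient raises theta/beta ratio with class id", {
  specs <- default_fatigue_classes()
  theta <- vapply(specs, function(s) s$band_powers$theta, 0)
  beta <- vapply(specs, function(s) s$band_powers$beta, 0)
  expect_true(all(diff(theta) >= 0))
  expect_true(all(diff(beta) <= 0))
  # realized band-power ratio, periodogram oracle averaged over seeds
  ratio <- function(spec) {
    mean(vapply(1:100, function(s) {
      x <- generate_window(spec, 1, 1250, 250, seed = s)[1, ]
      band_power(x, 250, c(4, 8)) / band_power(x, 250, c(13, 30))
    }, 0))
  }
  ratios <- vapply(specs, ratio, 0)
  expect_true(all(diff(ratios) > 0))
  expect_gt(ratios[5], ratios[1])
})

test_that("cohort generation is balanced, labeled and reproducible", {
  co <- cohort_spec(n_windows_per_class = 10, seed = 5, fs = 128, window_s = 0.5)
  ds <- generate_cohort(co)
  expect_s3_class(ds, "windowed_dataset")
  expect_equal(n_windows(ds), 50)
  expect_equal(unname(table(ds$labels)), rep(10L, 5), ignore_attr = TRUE)
  ds2 <- generate_cohort(co)
  expect_identical(ds$data, ds2$data)
  two <- generate_cohort(cohort_spec(classes = two_class_specs(),
                                     n_windows_per_class = 1, fs = 128,
                                     window_s = 0.5, seed = 1))
  expect_equal(n_windows(two), 2)
  expect_error(cohort_spec(classes = list(default_fatigue_classes()[[1]],
                                          default_fatigue_classes()[[1]])),
               "duplicate")
  expect_error(cohort_spec(fs = 50), "band edge")
})

test_that("class 0 vs class 4 is linearly separable from band powers", {
  ds <- small_cohort(n = 100, seed = 9)
  sp <- split_dataset(ds, seed = 2)
  feats <- band_power_features(sp$train)
  fit <- MASS::lda(feats, grouping = factor(sp$train$labels))
  pred <- predict(fit, band_power_features(sp$val))$class
  expect_gte(mean(pred == factor(sp$val$labels)), 0.9)
})

test_that("mains injection adds a tone at f0 and validates Nyquist", {
  w <- generate_window(default_fatigue_classes()[[1]], 2, 1250, 250, seed = 3)
  expect_identical(inject_mains(w, 250, 50, amplitude = 0), w)
  peak_power <- function(x, f0, fs) {
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n^2
    p[which.min(abs((seq_len(n) - 1) * fs / n - f0))]
  }
  wi <- inject_mains(w, 250, 50, amplitude = 10, seed = 4)
  expect_gt(peak_power(wi[1, ], 50, 250), peak_power(w[1, ], 50, 250))
  expect_equal(dim(wi), dim(w))
  expect_error(inject_mains(w, 250, f0 = 130), "Nyquist|strictly")
})

test_that("white noise is added at the exact requested SNR", {
  w <- generate_window(default_fatigue_classes()[[2]], 4, 1250, 250, seed = 1)
  for (snr in c(60, 10, 0, -10)) {
    noisy <- add_white_noise_snr(w, snr, seed = 11)
    p_noise <- mean((noisy - w)^2)
    measured <- 10 * log10(mean(w^2) / p_noise)
    expect_lt(abs(measured - snr), 0.1)
  }
  hi <- add_white_noise_snr(w, 60, seed = 2)
  expect_false(identical(hi, w))
  expect_lt(mean((hi - w)^2) / mean(w^2), 2e-6)
  expect_error(add_white_noise_snr(matrix(0, 2, 10), 10), "all-zero")
  expect_identical(add_white_noise_snr(w, 5, seed = 3),
                   add_white_noise_snr(w, 5, seed = 3))
})

test_that("inter-channel correlation is strictly between 0 and 1", {
  ds <- small_cohort(n = 30, seed = 21)
  A <- correlation_adjacency(ds)
  off <- A[upper.tri(A)]
  expect_true(all(off > 0 & off < 1))
})

test_that("cohort CSV round trip preserves data and provenance", {
  ds <- small_cohort(n = 3, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort_csv(ds, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$data, ds$data, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$fs, ds$fs)
  expect_equal(back$provenance$seed, ds$provenance$seed)
})
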