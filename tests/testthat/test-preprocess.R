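make_recording <- function(n_ch = 19, n_s = 2500, fs = 250, seed = 1) {
  set.seed(seed)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
              "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")[seq_len(n_ch)]
  eeg_recording(matrix(rnorm(n_ch * n_s), n_ch), labels, fs)
}

test_that("channel selection reorders, is idempotent, and names missing channels", {
  rec <- make_recording()
  sel <- select_channels(rec)
  expect_equal(sel$channel_labels, c("P4", "C3", "O1", "O2"))
  expect_equal(nrow(sel$data), 4)
  expect_equal(sel$data[1, ], rec$data[16, ])
  # case-insensitive and identity on an already-selected recording
  again <- select_channels(sel, c("p4", "c3", "o1", "o2"))
  expect_equal(again$data, sel$data)
  expect_error(select_channels(sel, "Cz"), "Cz")
})

test_that("notch filter attenuates the mains tone and spares the passband", {
  fs <- 250
  t <- (0:4999) / fs
  tone50 <- sin(2 * pi * 50 * t)
  expect_lt(sd(notch_filter(tone50, fs)) / sd(tone50), 0.1)
  tone10 <- sin(2 * pi * 10 * t)
  ratio <- sd(notch_filter(tone10, fs)) / sd(tone10)
  expect_lt(abs(20 * log10(ratio)), 1)
  # matrix input keeps shape; channels filtered independently
  m <- rbind(tone50, tone10)
  out <- notch_filter(m, fs)
  expect_equal(dim(out), dim(m))
  expect_error(notch_filter(tone10, fs, f0 = 130), "Nyquist")
})

test_that("notch analytic response matches an impulse-response FFT oracle", {
  fs <- 250
  n <- 8192
  d <- eegfatigue:::design_notch(50, fs, Q = 30)
  h <- signal::filter(d$b, d$a, c(1, rep(0, n - 1)))
  H_meas <- Mod(fft(h))
  f <- (seq_len(n) - 1) * fs / n
  sel <- round(seq(2, n / 2, length.out = 64))
  expect_lt(max(abs(H_meas[sel] - Mod(notch_response(f[sel], fs)))), 1e-6)
})

test_that("bandpass matches the closed-form Butterworth factor response", {
  fs <- 250
  f <- seq(0.5, 110, length.out = 200)
  warp <- function(f) tan(pi * f / fs)            # bilinear prewarping
  mag_oracle <- 1 / sqrt(1 + (warp(0.02) / warp(f))^4) *
    1 / sqrt(1 + (warp(f) / warp(50))^4)
  expect_lt(max(abs(Mod(bandpass_response(f, fs)) - mag_oracle)), 1e-4)
  # -3 dB at the upper edge
  expect_lt(abs(Mod(bandpass_response(50, fs)) - 1 / sqrt(2)), 1e-6)
})

test_that("bandpass passes 10 Hz, rejects 80 Hz, and removes DC", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  tone10 <- sin(2 * pi * 10 * t)
  r10 <- sd(bandpass_butterworth(tone10, fs)) / sd(tone10)
  expect_lt(abs(20 * log10(r10)), 1)
  tone80 <- sin(2 * pi * 80 * t)
  r80 <- sd(bandpass_butterworth(tone80, fs)) / sd(tone80)
  expect_lt(20 * log10(r80), -12)
  dc <- rep(5, length(t))
  expect_lt(abs(mean(bandpass_butterworth(dc, fs))), 0.5)
  expect_error(bandpass_butterworth(tone10, fs, hi = 130), "Nyquist")
})

test_that("filters are linear and shape-preserving", {
  fs <- 250
  set.seed(3)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(max(abs(notch_filter(a + b, fs) -
                      (notch_filter(a, fs) + notch_filter(b, fs)))), 1e-8)
  expect_lt(max(abs(bandpass_butterworth(a + b, fs) -
                      (bandpass_butterworth(a, fs) + bandpass_butterworth(b, fs)))), 1e-8)
  expect_length(notch_filter(a, fs), 1000)
})

test_that("terminal window takes the final samples with 0-based provenance", {
  fs <- 250
  rec <- make_recording(n_ch = 4, n_s = 20 * 60 * fs)
  w <- extract_terminal_window(rec, 5)
  expect_equal(ncol(w$data), 1250)
  expect_equal(w$interval, c(298750, 300000))
  expect_equal(w$data, rec$data[, 298751:300000])
  whole <- extract_terminal_window(make_recording(n_ch = 2, n_s = 1250), 5)
  expect_equal(ncol(whole$data), 1250)
  expect_equal(whole$interval, c(0, 1250))
  expect_error(extract_terminal_window(make_recording(n_ch = 2, n_s = 1000), 5),
               "too short")
})

test_that("min-max normalization maps to [0,1], preserves order, handles constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(3, 3, 3)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(5)
  x <- rnorm(200)
  nx <- minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(cor(rank(x), rank(nx)), 1)
  # affine invariance: minmax(a x + b) == minmax(x) for a > 0
  expect_equal(minmax_normalize(3.7 * x + 11), nx, tolerance = 1e-12)
  expect_error(minmax_normalize(c(1, NA)), "finite")
})

test_that("full conditioning chain yields finite windows bounded in [0,1]", {
  ds <- small_cohort(n = 4)
  out <- preprocess_windows(ds)
  expect_true(all(is.finite(out$data)))
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 1)
  expect_equal(dim(out$data), dim(ds$data))
})
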