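test_that("downsampled sine matches its closed form on the new grid", {
  t_in <- seq(0, 60 - 1 / 1024, by = 1 / 1024)
  rec <- eeg_recording(matrix(sin(2 * pi * 5 * t_in), 1), 1024, "C3")
  out <- resample_recording(rec, 100)
  expect_equal(ncol(out$signal), 6000L)   # round(n * 100 / 1024)
  t_out <- (seq_len(ncol(out$signal)) - 1) / 100
  expect_gte(cor(out$signal[1, ], sin(2 * pi * 5 * t_out)), 0.999)
})

test_that("resampling to the same rate is the identity; upsampling rejected", {
  rec <- eeg_recording(matrix(rnorm(500), 1), 100, "C3")
  expect_identical(resample_recording(rec, 100)$signal, rec$signal)
  expect_error(resample_recording(rec, 200), "upsampling")
})

test_that("duration is preserved through resampling within one sample", {
  for (dur in c(10, 33.3, 60)) {
    n_in <- round(dur * 1024)
    rec <- eeg_recording(matrix(rnorm(n_in), 1), 1024, "C3")
    out <- resample_recording(rec, 100)
    expect_lte(abs(ncol(out$signal) / 100 - n_in / 1024), 1 / 100)
  }
})

test_that("designed band-pass meets its frequency-response contracts", {
  h <- design_bandpass_fir(100)
  expect_equal(length(h) %% 2, 1)   # linear phase, odd length
  nfft <- 2^16
  gain <- abs(stats::fft(c(h, numeric(nfft - length(h)))))[1:(nfft / 2)]
  f <- (seq_len(nfft / 2) - 1) * 100 / nfft
  gain_db_at <- function(fq) {
    20 * log10(stats::approx(f, gain, fq)$y)
  }
  # -6 dB points at the band edges
  expect_lt(abs(gain_db_at(0.3) + 6), 1.5)
  expect_lt(abs(gain_db_at(30) + 6), 1.5)
  # passband flat within +/-1 dB over [1, 28] Hz
  pb <- f >= 1 & f <= 28
  expect_lt(max(abs(20 * log10(gain[pb]))), 1)
  # stopband: >= 40 dB down at 45 Hz
  expect_lt(gain_db_at(45), -40)
})

test_that("filtering is zero phase, length preserving and linear", {
  fs <- 100
  n <- 6000
  t <- (seq_len(n) - 1) / fs
  x13 <- sin(2 * pi * 13 * t)
  rec <- eeg_recording(matrix(x13, 1), fs, "C3")
  out <- bandpass_fir(rec)
  expect_equal(ncol(out$signal), n)
  core <- 1000:5000   # away from edge transients
  # mid-sigma tone passes within 1 dB and without phase shift
  rms_ratio_db <- 20 * log10(sqrt(mean(out$signal[1, core]^2)) /
                               sqrt(mean(x13[core]^2)))
  expect_lt(abs(rms_ratio_db), 1)
  expect_gt(cor(out$signal[1, core], x13[core]), 0.999)
  # linearity
  y <- rnorm(n)
  rec_y <- eeg_recording(matrix(y, 1), fs, "C3")
  rec_mix <- eeg_recording(matrix(2 * x13 - 3 * y, 1), fs, "C3")
  lhs <- bandpass_fir(rec_mix)$signal[1, ]
  rhs <- 2 * out$signal[1, ] - 3 * bandpass_fir(rec_y)$signal[1, ]
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
})

test_that("DC offsets are removed by the band-pass", {
  fs <- 100
  x <- rnorm(6000) + 10
  out <- bandpass_fir(eeg_recording(matrix(x, 1), fs, "C3"))
  # compare against the zero-mean input filtered identically: in steady
  # state (away from the zero-padded edge transients) the DC component
  # contributes nothing
  out0 <- bandpass_fir(eeg_recording(matrix(x - 10, 1), fs, "C3"))
  core <- 1200:4800   # > filter length away from either end
  expect_lt(abs(mean(out$signal[1, core]) - mean(out0$signal[1, core])),
            1e-3)
  # the filter's own DC gain is essentially zero
  h <- design_bandpass_fir(fs)
  expect_lt(abs(sum(h)), 1e-3)
})

test_that("too-short recordings are rejected with a padding hint", {
  rec <- eeg_recording(matrix(rnorm(500), 1), 100, "C3")
  expect_error(bandpass_fir(rec), "filter length")
})

test_that("z-scoring normalizes each channel independently and exactly", {
  sig <- rbind(5 * rnorm(1000) + 3, 0.2 * rnorm(1000) - 7)
  rec <- eeg_recording(sig, 100, c("C3", "C4"))
  z <- zscore_recording(rec)
  for (i in 1:2) {
    expect_lt(abs(mean(z$signal[i, ])), 1e-10)
    expect_lt(abs(stats::sd(z$signal[i, ]) - 1), 1e-10)
  }
  # affine invariance
  rec2 <- eeg_recording(rbind(2 * sig[1, ] + 5, sig[2, ]), 100,
                        c("C3", "C4"))
  z2 <- zscore_recording(rec2)
  expect_equal(z2$signal[1, ], z$signal[1, ], tolerance = 1e-12)
  # zero-variance channel is an error naming the channel
  flat <- eeg_recording(rbind(rnorm(100), rep(1, 100)), 100, c("C3", "C4"))
  expect_error(zscore_recording(flat), "C4")
})

test_that("the full chain resamples, filters and normalizes in order", {
  sim <- simulate_recording(test_config(duration = 120, seed = 13))
  pp <- preprocess_recording(sim$recording)
  expect_equal(pp$fs_hz, 100)
  expect_equal(ncol(pp$signal), 12000L)
  for (i in seq_along(pp$channels)) {
    expect_lt(abs(mean(pp$signal[i, ])), 1e-10)
    expect_lt(abs(stats::sd(pp$signal[i, ]) - 1), 1e-10)
  }
  expect_named(pp$meta, c("resample", "bandpass", "zscore"))
  # sigma-band concentration survives the chain
  ann <- sim$annotations[sim$annotations$channel == "C3", ]
  expect_gt(nrow(ann), 0)
  x <- pp$signal["C3", ]
  in_event <- rep(FALSE, length(x))
  for (j in seq_len(nrow(ann))) {
    in_event[(floor(ann$onset_s[j] * 100) + 1):
               floor((ann$onset_s[j] + ann$duration_s[j]) * 100)] <- TRUE
  }
  expect_gt(sigma_fraction(x[in_event], 100),
            sigma_fraction(x[!in_event], 100))
})

test_that("invalid band edges are rejected up front", {
  expect_error(preprocess_config(band_hz = c(30, 0.3)), "low < high")
  expect_error(preprocess_config(band_hz = c(0.3, 60)), "low < high")
})
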