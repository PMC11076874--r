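test_that("identical config and seed reproduce the recording bit for bit", {
  cfg <- test_config(duration = 30, seed = 11)
  a <- simulate_recording(cfg, "S01")
  b <- simulate_recording(cfg, "S01")
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$annotations, b$annotations)
})

test_that("zero spindle rate yields pure background and no annotations", {
  cfg <- test_config(duration = 20, seed = 2, rate = 0)
  sim <- simulate_recording(cfg)
  expect_equal(nrow(sim$annotations), 0L)
  # background-only: sigma fraction is low everywhere
  expect_lt(sigma_fraction(sim$recording$signal[1, ], cfg$fs_hz), 0.3)
})

test_that("event counts are Poisson with mean rate x duration", {
  # one channel, low fs: count statistics do not depend on the waveform
  n_seeds <- 200
  dur <- 600
  rate <- 3
  counts <- vapply(seq_len(n_seeds), function(s) {
    cfg <- generator_config(fs_hz = 64, record_duration_s = dur,
                            channels = "C3", spindle_rate_per_min = rate,
                            seed = s)
    nrow(simulate_recording(cfg)$annotations)
  }, 0)
  mu <- rate * dur / 60                      # 30
  se <- sqrt(mu / n_seeds)                   # Poisson sd / sqrt(n)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("annotations respect record bounds and the minimum gap", {
  cfg <- test_config(duration = 90, seed = 5)
  sim <- simulate_recording(cfg)
  ann <- sim$annotations
  expect_true(all(ann$onset_s >= 0))
  expect_true(all(ann$onset_s + ann$duration_s <= cfg$record_duration_s))
  for (ch in unique(ann$channel)) {
    a <- ann[ann$channel == ch, ]
    a <- a[order(a$onset_s), ]
    if (nrow(a) > 1) {
      gaps <- a$onset_s[-1] - (a$onset_s[-nrow(a)] + a$duration_s[-nrow(a)])
      expect_true(all(gaps >= cfg$min_gap_s))
    }
  }
})

test_that("event segments carry their energy in the sigma band", {
  cfg <- test_config(duration = 60, seed = 3, noise_scale_uv = 1)
  sim <- simulate_recording(cfg)
  ann <- sim$annotations[sim$annotations$channel == "C3", ]
  expect_gt(nrow(ann), 0)
  fs <- cfg$fs_hz
  x <- sim$recording$signal["C3", ]
  for (j in seq_len(nrow(ann))) {
    idx <- (floor(ann$onset_s[j] * fs) + 1):floor((ann$onset_s[j] +
                                                     ann$duration_s[j]) * fs)
    p <- abs(stats::fft(x[idx] - mean(x[idx])))^2
    f <- (seq_along(idx) - 1) * fs / length(idx)
    peak <- f[f <= fs / 2][which.max(p[f <= fs / 2])]
    expect_gte(peak, cfg$regime$freq_range_hz[1] - 1)
    expect_lte(peak, cfg$regime$freq_range_hz[2] + 1)
  }
})

test_that("sigma-band power is concentrated in annotated intervals", {
  # spectral contract at the default noise scale
  cfg <- test_config(duration = 120, seed = 9)
  sim <- simulate_recording(cfg)
  fs <- cfg$fs_hz
  for (ch in cfg$channels) {
    x <- sim$recording$signal[ch, ]
    ann <- sim$annotations[sim$annotations$channel == ch, ]
    expect_gt(nrow(ann), 0)
    in_event <- rep(FALSE, length(x))
    for (j in seq_len(nrow(ann))) {
      in_event[(floor(ann$onset_s[j] * fs) + 1):
                 floor((ann$onset_s[j] + ann$duration_s[j]) * fs)] <- TRUE
    }
    expect_gt(sigma_fraction(x[in_event], fs),
              sigma_fraction(x[!in_event], fs))
  }
})

test_that("insomnia regime events are shorter than normal ones", {
  dur_mean <- function(regime) {
    coh <- simulate_cohort(3, test_config(duration = 120, regime = regime,
                                          seed = 21))
    mean(unlist(lapply(coh, function(s) s$annotations$duration_s)))
  }
  expect_lt(dur_mean("insomnia"), dur_mean("normal"))
})

test_that("cohort subjects are distinct but individually reproducible", {
  cfg <- test_config(duration = 20, seed = 8)
  coh <- simulate_cohort(3, cfg)
  ids <- vapply(coh, function(s) s$recording$subject_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  expect_false(identical(coh[[1]]$recording$signal,
                         coh[[2]]$recording$signal))
  # composition identity: cohort of one equals the derived single call
  one <- simulate_cohort(1, cfg)[[1]]
  cfg1 <- cfg
  cfg1$seed <- spindlecnn:::derive_seed(cfg$seed, "S01")
  direct <- simulate_recording(cfg1, "S01")
  expect_identical(one$recording$signal, direct$recording$signal)
  expect_identical(one$annotations, direct$annotations)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(fs_hz = 20), "Nyquist|twice")
  expect_error(spindle_regime("normal", freq_range_hz = c(9, 16)), "sigma")
  expect_error(spindle_regime("normal", duration_range_s = c(2, 1)),
               "interval")
  # event load that cannot fit the record
  expect_error(generator_config(record_duration_s = 60,
                                spindle_rate_per_min = 40), "fit")
})
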