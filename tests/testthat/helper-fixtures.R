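# Shared fixtures, generated in code. Unit tests use a reduced sampling
# rate (256 Hz) and short records so the suite stays fast; the acceptance
# tests use the full default conditions.

test_config <- function(duration = 120, regime = "normal", seed = 1L,
                        fs = 256, rate = 3, channels = c("C3", "C4"),
                        ...) {
  generator_config(fs_hz = fs, record_duration_s = duration,
                   channels = channels, spindle_rate_per_min = rate,
                   regime = spindle_regime(regime), seed = seed, ...)
}

test_cohort <- function(n_subjects = 3, duration = 120, regime = "normal",
                        seed = 1L, preprocessed = TRUE, ...) {
  cohort <- simulate_cohort(n_subjects,
                            test_config(duration, regime, seed, ...),
                            id_prefix = if (regime == "insomnia") "I" else "S")
  if (preprocessed) {
    cohort <- lapply(cohort, function(s) {
      s$recording <- preprocess_recording(s$recording)
      s
    })
  }
  cohort
}

test_window_set <- function(n_subjects = 3, duration = 120,
                            regime = "normal", seed = 1L, ...) {
  suppressWarnings(
    build_window_set(test_cohort(n_subjects, duration, regime, seed, ...),
                     seed = seed)
  )
}

# Small architecture for gradient and mechanics tests (keeps the mandated
# 5-block / 2-pool structure at a fraction of the default size).
tiny_spec <- function(input_len = 40) {
  cnn_spec(channels = c(2, 2, 3, 3, 4), kernels = c(3, 3, 3, 3, 3),
           hidden = 5, input_len = input_len)
}

# Band power in [lo, hi] Hz of a vector via the periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi & f <= fs / 2])
}

# Ratio of sigma-band (11-16 Hz) power to broadband (0.3-30 Hz) power.
sigma_fraction <- function(x, fs) {
  band_power(x, fs, 11, 16) / band_power(x, fs, 0.3, 30)
}

flatten_params <- function(params) {
  unlist(params, use.names = TRUE)
}
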