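#' Spindle regime description
#'
#' A regime bundles the distributional parameters of the spindle events a
#' synthetic cohort contains. Two presets mirror the qualitative contrast
#' between healthy sleepers and insomnia patients: normal spindles are
#' ~0.8-1.5 s bursts peaking at 20-30 uV and symmetric about zero, while
#' insomnia-like spindles are shorter (~0.4-0.8 s), span a larger amplitude
#' range, and ride on a positive baseline offset so the waveform is
#' asymmetric (roughly -10..+40 uV rather than +/-30 uV).
#'
#' @param regime preset name, `"normal"` or `"insomnia"`. Individual fields
#'   below override the preset.
#' @param freq_range_hz closed interval of spindle carrier frequency in Hz;
#'   must lie inside the sigma band \[11, 16\].
#' @param duration_range_s closed interval of event duration in seconds.
#' @param amplitude_range_uv closed interval of the envelope peak amplitude
#'   in microvolts.
#' @param baseline_offset_uv interval from which a per-event DC offset is
#'   drawn (scaled by the envelope so the event stays continuous); `c(0, 0)`
#'   for the normal preset, `c(0, 10)` for the insomnia preset.
#' @param envelope envelope shape: `"hann"` (waxing-waning, default),
#'   `"gaussian"`, or `"sine2"` (squared sine).
#' @return an object of class `spindle_regime`.
#' @examples
#' spindle_regime("insomnia")
#' spindle_regime("normal", freq_range_hz = c(12, 14))
#' @export
spindle_regime <- function(regime = c("normal", "insomnia"),
                           freq_range_hz = NULL,
                           duration_range_s = NULL,
                           amplitude_range_uv = NULL,
                           baseline_offset_uv = NULL,
                           envelope = c("hann", "gaussian", "sine2")) {
  regime <- match.arg(regime)
  envelope <- match.arg(envelope)
  preset <- switch(regime,
    normal = list(freq = c(11, 16), dur = c(0.8, 1.5), amp = c(20, 30),
                  off = c(0, 0)),
    insomnia = list(freq = c(11, 16), dur = c(0.4, 0.8), amp = c(25, 50),
                    off = c(0, 10))
  )
  out <- structure(list(
    name = regime,
    freq_range_hz = as.numeric(freq_range_hz %||% preset$freq),
    duration_range_s = as.numeric(duration_range_s %||% preset$dur),
    amplitude_range_uv = as.numeric(amplitude_range_uv %||% preset$amp),
    baseline_offset_uv = as.numeric(baseline_offset_uv %||% preset$off),
    envelope = envelope
  ), class = "spindle_regime")
  validate_regime(out)
  out
}

validate_regime <- function(r) {
  chk_interval <- function(x, nm, positive = TRUE) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
      stopf("%s must be a finite interval c(lower, upper)", nm)
    }
    if (positive && x[1] <= 0) stopf("%s must be positive", nm)
  }
  chk_interval(r$freq_range_hz, "freq_range_hz")
  chk_interval(r$duration_range_s, "duration_range_s")
  chk_interval(r$amplitude_range_uv, "amplitude_range_uv")
  chk_interval(r$baseline_offset_uv, "baseline_offset_uv", positive = FALSE)
  if (r$freq_range_hz[1] < 11 || r$freq_range_hz[2] > 16) {
    stopf("freq_range_hz must lie inside the sigma band [11, 16] Hz")
  }
  invisible(r)
}

#' @export
print.spindle_regime <- function(x, ...) {
  cat(sprintf("Spindle regime '%s': %g-%g Hz, %g-%g s, peak %g-%g uV",
              x$name, x$freq_range_hz[1], x$freq_range_hz[2],
              x$duration_range_s[1], x$duration_range_s[2],
              x$amplitude_range_uv[1], x$amplitude_range_uv[2]))
  if (any(x$baseline_offset_uv != 0)) {
    cat(sprintf(", offset %g-%g uV", x$baseline_offset_uv[1],
                x$baseline_offset_uv[2]))
  }
  cat(sprintf(", %s envelope\n", x$envelope))
  invisible(x)
}

#' Synthetic polysomnography generator configuration
#'
#' @param fs_hz sampling rate in Hz (default 1024, typical of clinical PSG
#'   amplifiers).
#' @param record_duration_s total record length in seconds.
#' @param channels channel names; events are placed independently per
#'   channel (no cross-channel correlation).
#' @param spindle_rate_per_min Poisson event density per channel, events per
#'   minute.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param noise_scale_uv RMS of the background noise in microvolts.
#' @param min_gap_s minimum gap in seconds between consecutive events on the
#'   same channel.
#' @param regime a [spindle_regime()].
#' @param seed integer RNG seed; the whole recording is reproducible from it.
#' @return an object of class `generator_config`.
#' @examples
#' generator_config(record_duration_s = 120, seed = 1)
#' @export
generator_config <- function(fs_hz = 1024,
                             record_duration_s = 600,
                             channels = c("C3", "C4"),
                             spindle_rate_per_min = 3,
                             noise_exponent = 1,
                             noise_scale_uv = 10,
                             min_gap_s = 2,
                             regime = spindle_regime("normal"),
                             seed = 1L) {
  cfg <- structure(list(
    fs_hz = fs_hz, record_duration_s = record_duration_s,
    channels = as.character(channels),
    spindle_rate_per_min = spindle_rate_per_min,
    noise_exponent = noise_exponent, noise_scale_uv = noise_scale_uv,
    min_gap_s = min_gap_s, regime = regime, seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is_number(cfg$fs_hz) || cfg$fs_hz <= 0) stopf("fs_hz must be > 0")
  if (!inherits(cfg$regime, "spindle_regime")) {
    stopf("regime must be a spindle_regime object")
  }
  if (cfg$fs_hz <= 2 * cfg$regime$freq_range_hz[2]) {
    stopf("fs_hz (%g) must exceed twice the regime's upper frequency (%g Hz)",
          cfg$fs_hz, cfg$regime$freq_range_hz[2])
  }
  if (!is_number(cfg$record_duration_s) || cfg$record_duration_s <= 0) {
    stopf("record_duration_s must be > 0")
  }
  if (cfg$spindle_rate_per_min < 0) stopf("spindle_rate_per_min must be >= 0")
  if (cfg$noise_scale_uv < 0) stopf("noise_scale_uv must be >= 0")
  if (cfg$min_gap_s < 0) stopf("min_gap_s must be >= 0")
  if (length(cfg$channels) < 1L) stopf("at least one channel required")
  # capacity: the expected events, each occupying up to (max duration + gap),
  # must fit in the record with headroom for random placement
  lambda <- cfg$spindle_rate_per_min * cfg$record_duration_s / 60
  occupancy <- lambda * (cfg$regime$duration_range_s[2] + cfg$min_gap_s)
  if (occupancy > 0.8 * cfg$record_duration_s) {
    stopf(paste0("expected event load (%.1f s of events+gaps) cannot fit a ",
                 "%.0f s record; lower spindle_rate_per_min or min_gap_s"),
          occupancy, cfg$record_duration_s)
  }
  invisible(cfg)
}

#' Construct an EEG recording object
#'
#' @param signal channels x samples numeric matrix in microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param channels channel names, one per row of `signal`.
#' @param subject_id subject identifier.
#' @return an object of class `eeg_recording` with fields `signal`, `fs_hz`,
#'   `channels`, `subject_id`.
#' @export
eeg_recording <- function(signal, fs_hz, channels, subject_id = "S01") {
  signal <- as.matrix(signal)
  channels <- as.character(channels)
  if (nrow(signal) != length(channels)) {
    stopf("signal has %d rows but %d channel names given",
          nrow(signal), length(channels))
  }
  if (!is_number(fs_hz) || fs_hz <= 0) stopf("fs_hz must be > 0")
  rownames(signal) <- channels
  structure(list(signal = signal, fs_hz = fs_hz, channels = channels,
                 subject_id = as.character(subject_id), meta = list()),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording '%s': %d channel(s) [%s], %.1f s @ %g Hz\n",
              x$subject_id, length(x$channels),
              paste(x$channels, collapse = ", "),
              ncol(x$signal) / x$fs_hz, x$fs_hz))
  if (length(x$meta)) {
    cat(sprintf("  processing: %s\n", paste(names(x$meta), collapse = " -> ")))
  }
  invisible(x)
}

# 1/f^beta background noise via FFT magnitude shaping of white Gaussian
# noise, normalized to the requested RMS. beta = 0 gives white noise.
pink_noise <- function(n, exponent = 1, scale = 1) {
  if (scale == 0 || n == 0L) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent == 0) return(scale * w / stats::sd(w))
  sp <- stats::fft(w)
  # frequency bin magnitudes (symmetric); DC removed
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  shape <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  scale * x / stats::sd(x)
}

spindle_envelope <- function(n, type = "hann") {
  t <- seq_len(n)
  switch(type,
    hann = 0.5 - 0.5 * cos(2 * pi * (t - 1) / (n - 1)),
    gaussian = exp(-0.5 * ((t - (n + 1) / 2) / (n / 6))^2),
    sine2 = sin(pi * (t - 1) / (n - 1))^2,
    stopf("unknown envelope '%s'", type)
  )
}

# Place n_events onsets (seconds) into [0, dur - d] with a minimum gap
# between events; rejection sampling, seeded by the caller's RNG state.
place_events <- function(n_events, record_s, durations, min_gap) {
  onsets <- numeric(0)
  kept_d <- numeric(0)
  for (i in seq_len(n_events)) {
    d <- durations[i]
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      o <- stats::runif(1, 0, record_s - d)
      ok <- all(o + d + min_gap <= onsets | o >= onsets + kept_d + min_gap)
      if (ok) {
        onsets <- c(onsets, o); kept_d <- c(kept_d, d)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warnf("could not place event %d of %d at min_gap_s; event dropped",
            i, n_events)
    }
  }
  ord <- order(onsets)
  list(onset_s = onsets[ord], duration_s = kept_d[ord])
}

#' Simulate a polysomnography recording with annotated spindles
#'
#' Generates 1/f^beta background noise per channel and adds Poisson-placed
#' spindle events: each event is a sinusoid whose frequency, peak amplitude
#' and duration are drawn uniformly from the regime's ranges, multiplied by
#' the regime envelope (plus an envelope-scaled baseline offset for
#' asymmetric regimes). Events on the same channel never overlap and respect
#' the configured minimum gap. The returned annotations exactly describe the
#' injected events. Fully reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @param subject_id subject identifier stored in the recording and
#'   annotation rows.
#' @return a list with elements `recording` (an [eeg_recording()]) and
#'   `annotations` (a data frame with columns `subject_id`, `channel`,
#'   `onset_s`, `duration_s`; onset is 0-based seconds from recording start,
#'   event interval is half-open `[onset, onset + duration)`).
#' @examples
#' sim <- simulate_recording(generator_config(record_duration_s = 60, seed = 1))
#' sim$recording
#' head(sim$annotations)
#' @export
simulate_recording <- function(config, subject_id = "S01") {
  validate_generator_config(config)
  fs <- config$fs_hz
  n <- round(config$record_duration_s * fs)
  reg <- config$regime
  with_seed(config$seed, {
    sig <- matrix(0, length(config$channels), n)
    ann <- list()
    for (ci in seq_along(config$channels)) {
      x <- pink_noise(n, config$noise_exponent, config$noise_scale_uv)
      lambda <- config$spindle_rate_per_min * config$record_duration_s / 60
      n_ev <- if (lambda > 0) stats::rpois(1, lambda) else 0L
      if (n_ev > 0) {
        durs <- stats::runif(n_ev, reg$duration_range_s[1],
                             reg$duration_range_s[2])
        ev <- place_events(n_ev, config$record_duration_s, durs,
                           config$min_gap_s)
        for (j in seq_along(ev$onset_s)) {
          o <- ev$onset_s[j]; d <- ev$duration_s[j]
          f <- stats::runif(1, reg$freq_range_hz[1], reg$freq_range_hz[2])
          a <- stats::runif(1, reg$amplitude_range_uv[1],
                            reg$amplitude_range_uv[2])
          off <- stats::runif(1, reg$baseline_offset_uv[1],
                              reg$baseline_offset_uv[2])
          phi <- stats::runif(1, 0, 2 * pi)
          i0 <- floor(o * fs) + 1L
          i1 <- min(n, floor((o + d) * fs))
          idx <- i0:i1
          tt <- (idx - 1) / fs - o
          env <- spindle_envelope(length(idx), reg$envelope)
          x[idx] <- x[idx] + a * env * sin(2 * pi * f * tt + phi) + off * env
        }
        ann[[ci]] <- data.frame(
          subject_id = subject_id, channel = config$channels[ci],
          onset_s = ev$onset_s, duration_s = ev$duration_s,
          stringsAsFactors = FALSE
        )
      }
      sig[ci, ] <- x
    }
    annotations <- if (length(ann)) {
      do.call(rbind, ann)
    } else {
      empty_annotations()
    }
    rownames(annotations) <- NULL
    list(recording = eeg_recording(sig, fs, config$channels, subject_id),
         annotations = annotations)
  })
}

empty_annotations <- function() {
  data.frame(subject_id = character(0), channel = character(0),
             onset_s = numeric(0), duration_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of subjects
#'
#' One recording per subject, all sharing the cohort regime and generator
#' settings but with per-subject seeds derived from the subject id (so the
#' cohort is reproducible and invariant to subject ordering).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config a [generator_config()]; its `seed` is the cohort base seed.
#' @param id_prefix prefix for generated subject ids.
#' @return a list of length `n_subjects`; each element is the
#'   `list(recording, annotations)` returned by [simulate_recording()].
#' @examples
#' cohort <- simulate_cohort(2, generator_config(record_duration_s = 60, seed = 3))
#' sapply(cohort, function(s) s$recording$subject_id)
#' @export
simulate_cohort <- function(n_subjects, config, id_prefix = "S") {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("%s%02d", id_prefix, i)
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, sid)
    simulate_recording(cfg_i, subject_id = sid)
  })
}
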