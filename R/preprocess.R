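# Preprocessing chain: polyphase downsample -> zero-phase Hamming FIR
# band-pass -> per-channel z-score. Annotation times are seconds, so they
# survive resampling unchanged.

#' Preprocessing configuration
#'
#' @param target_fs_hz output sampling rate in Hz (default 100).
#' @param band_hz band-pass edges `c(low, high)` in Hz; the designed filter
#'   has its -6 dB points at these edges (default `c(0.3, 30)`).
#' @param fir_window FIR design window; only `"hamming"` is implemented.
#' @param transition_bw_hz transition widths `c(low_side, high_side)` in Hz.
#'   Defaults: low side `min(low_edge, 2)` (0.3 Hz at the default band);
#'   high side `min(0.25 * high_edge, nyquist - high_edge, 5)` (5 Hz), which
#'   keeps the passband within +/-1 dB up to 28 Hz while retaining >= 40 dB
#'   stopband attenuation by 35 Hz.
#' @param zscore_scope `"per_channel_recording"` (default; each channel is
#'   normalized over the whole recording) or `"per_window"` (normalization
#'   is deferred to window extraction).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs_hz = 100,
                              band_hz = c(0.3, 30),
                              fir_window = "hamming",
                              transition_bw_hz = NULL,
                              zscore_scope = c("per_channel_recording",
                                               "per_window")) {
  zscore_scope <- match.arg(zscore_scope)
  if (!identical(fir_window, "hamming")) {
    stopf("only the 'hamming' FIR window is implemented")
  }
  band_hz <- as.numeric(band_hz)
  if (length(band_hz) != 2L || !all(is.finite(band_hz)) ||
      band_hz[1] <= 0 || band_hz[1] >= band_hz[2] ||
      band_hz[2] >= target_fs_hz / 2) {
    stopf("band_hz must satisfy 0 < low < high < target_fs_hz / 2")
  }
  if (is.null(transition_bw_hz)) {
    transition_bw_hz <- c(
      min(band_hz[1], 2),
      min(0.25 * band_hz[2], target_fs_hz / 2 - band_hz[2], 5)
    )
  }
  structure(list(target_fs_hz = target_fs_hz, band_hz = band_hz,
                 fir_window = fir_window,
                 transition_bw_hz = as.numeric(transition_bw_hz),
                 zscore_scope = zscore_scope),
            class = "preprocess_config")
}

# Greatest common divisor (Euclid), used to reduce the resampling ratio.
gcd <- function(a, b) {
  while (b != 0) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

# Polyphase FIR resampling of a vector by rational factor p/q with exact
# compensation of the (linear-phase) anti-alias filter's group delay.
# The filter is a Hamming-windowed sinc at the upsampled rate with cutoff
# min(input, output) Nyquist; output m is the dot product of the phase-
# (m*q + delay) mod p subfilter with the input around sample (m*q + delay)
# div p, so only the needed outputs are computed.
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (p == q) return(x)
  n <- length(x)
  half <- 5L * max(p, q)
  nh <- 2L * half + 1L
  fc <- min(1 / p, 1 / q)  # fraction of upsampled Nyquist
  h <- as.numeric(signal::fir1(nh - 1L, fc, type = "low",
                               window = signal::hamming(nh))) * p
  n_out <- round(n * p / q)
  m <- 0:(n_out - 1L)
  idx <- m * q + half
  r <- idx %% p
  b <- idx %/% p
  gl <- ceiling(nh / p)
  xx <- c(numeric(gl), x, numeric(gl))
  y <- numeric(n_out)
  for (ph in unique(r)) {
    g <- h[seq(ph + 1L, nh, by = p)]
    sel <- which(r == ph)
    gather <- outer(b[sel] + gl + 1L, seq_along(g) - 1L, "-")
    y[sel] <- matrix(xx[gather], nrow = length(sel)) %*% g
  }
  y
}

#' Downsample a recording
#'
#' Anti-alias filtered polyphase resampling to `target_fs_hz`. The output
#' has `round(n * target / source)` samples per channel. Upsampling is
#' rejected. Annotations (in seconds) remain valid unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param target_fs_hz target rate in Hz (must be <= the recording's rate).
#' @return the resampled [eeg_recording()].
#' @export
resample_recording <- function(recording, target_fs_hz = 100) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  if (target_fs_hz > fs) {
    stopf("upsampling (%g -> %g Hz) is not supported", fs, target_fs_hz)
  }
  if (target_fs_hz == fs) return(recording)
  # reduce target/source to integers p/q (rates scaled if non-integral)
  mult <- 1
  while (abs(fs * mult - round(fs * mult)) > 1e-9 ||
         abs(target_fs_hz * mult - round(target_fs_hz * mult)) > 1e-9) {
    mult <- mult * 10
    if (mult > 1e6) stopf("cannot express rate ratio %g/%g as a rational",
                          target_fs_hz, fs)
  }
  a <- round(target_fs_hz * mult); b <- round(fs * mult)
  g <- gcd(a, b)
  p <- a / g; q <- b / g
  out <- t(apply(recording$signal, 1L, resample_poly, p = p, q = q))
  rec <- eeg_recording(out, target_fs_hz, recording$channels,
                       recording$subject_id)
  rec$meta <- c(recording$meta,
                list(resample = list(from_fs_hz = fs, to_fs_hz = target_fs_hz,
                                     p = p, q = q)))
  rec
}

hamming_fir_length <- function(transition_hz, fs) {
  # Hamming design rule: transition width ~ 3.3 / N (normalized); odd length
  n <- ceiling(3.3 / (transition_hz / fs))
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

#' Design the Hamming-window FIR band-pass filter
#'
#' Built as the difference of two Hamming-windowed-sinc low-pass filters,
#' one per edge, each with a length set by its own transition width
#' (length = 3.3 / normalized transition width, forced odd). The -6 dB
#' points sit at the band edges; the filter is linear phase.
#'
#' @param fs sampling rate in Hz.
#' @param band_hz band edges `c(low, high)` in Hz.
#' @param transition_bw_hz transition widths `c(low_side, high_side)` in Hz
#'   (default as in [preprocess_config()]).
#' @return numeric vector of filter taps (odd length), with attributes
#'   `fs`, `band_hz`, `transition_bw_hz`.
#' @examples
#' h <- design_bandpass_fir(100)
#' length(h)
#' @export
design_bandpass_fir <- function(fs, band_hz = c(0.3, 30),
                                transition_bw_hz = NULL) {
  cfg <- preprocess_config(target_fs_hz = fs, band_hz = band_hz,
                           transition_bw_hz = transition_bw_hz)
  tw <- cfg$transition_bw_hz
  lp <- function(n, fc) {
    h <- as.numeric(signal::fir1(n - 1L, fc / (fs / 2), type = "low",
                                 window = signal::hamming(n)))
    h / sum(h)   # exactly unit DC gain, so the difference rejects DC exactly
  }
  n_lo <- hamming_fir_length(tw[1], fs)
  n_hi <- hamming_fir_length(tw[2], fs)
  h_hi <- lp(n_hi, band_hz[2])
  h_lo <- lp(n_lo, band_hz[1])
  n <- max(n_lo, n_hi)
  pad <- function(h) {
    d <- (n - length(h)) %/% 2L
    c(numeric(d), h, numeric(d))
  }
  h <- pad(h_hi) - pad(h_lo)
  attributes(h) <- list(fs = fs, band_hz = band_hz, transition_bw_hz = tw)
  h
}

# Zero-phase application of a linear-phase (odd length, symmetric) FIR:
# forward filtering with the group delay (n-1)/2 compensated by trimming.
# Ends assume zero signal beyond the record (documented edge behavior).
filter_zero_phase <- function(x, h) {
  d <- (length(h) - 1L) %/% 2L
  y <- signal::fftfilt(h, c(x, numeric(d)))
  y[(d + 1L):(d + length(x))]
}

#' Apply the band-pass FIR filter to a recording
#'
#' Zero-phase (forward filtering with group-delay compensation), so spindle
#' midpoints keep their temporal alignment. Output length equals input
#' length.
#'
#' @param recording an [eeg_recording()] already at the target rate.
#' @param config a [preprocess_config()] (its `band_hz` and
#'   `transition_bw_hz` are used at the recording's own rate).
#' @return the filtered [eeg_recording()].
#' @export
bandpass_fir <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  h <- design_bandpass_fir(recording$fs_hz, config$band_hz,
                           config$transition_bw_hz)
  if (ncol(recording$signal) < 3L * length(h)) {
    stopf(paste0("recording too short for the designed filter (%d samples, ",
                 "filter length %d); need >= 3 x filter length, consider ",
                 "padding or a wider transition band"),
          ncol(recording$signal), length(h))
  }
  out <- t(apply(recording$signal, 1L, filter_zero_phase, h = h))
  rec <- eeg_recording(out, recording$fs_hz, recording$channels,
                       recording$subject_id)
  rec$meta <- c(recording$meta,
                list(bandpass = list(band_hz = config$band_hz,
                                     transition_bw_hz = config$transition_bw_hz,
                                     fir_length = length(h))))
  rec
}

#' Z-score a recording per channel
#'
#' Each channel is centred and scaled to unit standard deviation over the
#' full recording. A zero-variance channel is an error naming the channel.
#'
#' @param recording an [eeg_recording()].
#' @return the normalized [eeg_recording()].
#' @export
zscore_recording <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig <- recording$signal
  for (i in seq_len(nrow(sig))) {
    s <- stats::sd(sig[i, ])
    if (!is.finite(s) || s == 0) {
      stopf("channel '%s' has zero variance; cannot z-score",
            recording$channels[i])
    }
    sig[i, ] <- (sig[i, ] - mean(sig[i, ])) / s
  }
  rec <- eeg_recording(sig, recording$fs_hz, recording$channels,
                       recording$subject_id)
  rec$meta <- c(recording$meta, list(zscore = list(scope = "per_channel_recording")))
  rec
}

#' Run the full preprocessing chain
#'
#' Composition, in order: [resample_recording()] to `target_fs_hz`, then
#' [bandpass_fir()], then (unless `zscore_scope = "per_window"`)
#' [zscore_recording()]. Parameters are logged into the recording's `meta`.
#'
#' @param recording an [eeg_recording()].
#' @param config a [preprocess_config()].
#' @return the preprocessed [eeg_recording()].
#' @examples
#' sim <- simulate_recording(generator_config(record_duration_s = 60, seed = 1))
#' pp <- preprocess_recording(sim$recording)
#' pp
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  rec <- resample_recording(recording, config$target_fs_hz)
  rec <- bandpass_fir(rec, config)
  if (config$zscore_scope == "per_channel_recording") {
    rec <- zscore_recording(rec)
  }
  rec
}
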