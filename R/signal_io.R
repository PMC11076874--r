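# Recording and annotation I/O.
#
# EDF support is implemented directly against the EDF specification
# (256-byte ASCII main header, 256 bytes per signal, data records of 16-bit
# little-endian integers mapped linearly between the digital and physical
# ranges). Only continuous single-rate recordings are handled; EDF+
# embedded annotations are out of scope (annotations travel as CSV).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers mapped over a fixed physical range,
#' so values are quantized to `diff(physical_range) / 65535` microvolts
#' (~0.006 uV at the default +/-200 uV range). Samples beyond a whole number
#' of 1 s data records are zero-padded; out-of-range samples are clipped
#' with a warning.
#'
#' @param recording an [eeg_recording()] in microvolts.
#' @param path output file path.
#' @param physical_range physical min/max in microvolts for the 16-bit
#'   mapping (default `c(-200, 200)`, generous headroom over typical
#'   +/-50 uV spindle EEG).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = c(-200, 200)) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  if (abs(fs - round(fs)) > 1e-9) {
    stopf("EDF writer requires an integer sampling rate; got %g", fs)
  }
  fs <- as.integer(round(fs))
  ns <- length(recording$channels)
  n <- ncol(recording$signal)
  n_rec <- as.integer(ceiling(n / fs))
  pmin_ <- physical_range[1]; pmax_ <- physical_range[2]
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id, 80),
    edf_pad(paste("Startdate 01-JAN-2000", recording$subject_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(recording$channels, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(pmin_, 8), ns), collapse = ""),
    paste(rep(edf_pad(pmax_, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  x <- recording$signal
  if (any(x < pmin_ | x > pmax_)) {
    warnf("samples outside the physical range [%g, %g] uV were clipped",
          pmin_, pmax_)
    x <- pmin(pmax(x, pmin_), pmax_)
  }
  dig <- round((x - pmin_) * scale) + dmin
  pad <- n_rec * fs - n
  if (pad > 0) {
    zero_dig <- as.integer(round((0 - pmin_) * scale) + dmin)
    dig <- cbind(dig, matrix(zero_dig, ns, pad))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  version <- rd(8); patient <- rd(80); rec_id <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  list(patient = patient, header_bytes = header_bytes, n_rec = n_rec,
       rec_dur = rec_dur, ns = ns, labels = labels, pmin = pmin_,
       pmax = pmax_, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @param channels optional channel names to keep, in the requested order
#'   (default: all channels in file order). A missing channel is an error.
#' @return an [eeg_recording()] in microvolts.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1L) {
    stopf(paste0("EDF file has per-channel sampling rates (%s samples/record)",
                 "; mixed rates are not supported (resample externally)"),
          paste(unique(h$spr), collapse = ", "))
  }
  fs <- h$spr[1] / h$rec_dur
  n <- h$n_rec * h$spr[1]
  sig <- matrix(0, h$ns, n)
  for (r in seq_len(h$n_rec)) {
    for (s in seq_len(h$ns)) {
      d <- readBin(con, "integer", n = h$spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      phys <- h$pmin[s] + (d - h$dmin[s]) *
        (h$pmax[s] - h$pmin[s]) / (h$dmax[s] - h$dmin[s])
      sig[s, ((r - 1L) * h$spr[s] + 1L):(r * h$spr[s])] <- phys
    }
  }
  rec <- eeg_recording(sig, fs, h$labels, subject_id = h$patient)
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}

select_channels <- function(recording, channels) {
  missing <- setdiff(channels, recording$channels)
  if (length(missing)) {
    stopf("channel(s) not present in recording: %s",
          paste(missing, collapse = ", "))
  }
  recording$signal <- recording$signal[match(channels, recording$channels), ,
                                       drop = FALSE]
  recording$channels <- channels
  recording
}

#' Write a recording as a CSV matrix
#'
#' Plain-text alternative to EDF: a comment line carries the metadata
#' (`# fs_hz=<rate> subject_id=<id>`), followed by one column per channel.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g subject_id=%s", recording$fs_hz,
                     recording$subject_id), con)
  utils::write.csv(as.data.frame(t(recording$signal)), con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV-matrix recording written by [write_recording_csv()]
#'
#' @inheritParams read_edf
#' @return an [eeg_recording()].
#' @export
read_recording_csv <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("fs_hz=([0-9.eE+-]+) subject_id=(.*)$", first))[[1]]
  if (length(m) != 3L) stopf("missing '# fs_hz=... subject_id=...' metadata line in %s", path)
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  rec <- eeg_recording(t(as.matrix(df)), as.numeric(m[2]), colnames(df),
                       subject_id = m[3])
  if (!is.null(channels)) rec <- select_channels(rec, channels)
  rec
}

#' Read a recording, dispatching on format
#'
#' @param path file path.
#' @param format `"auto"` (by file extension), `"edf"` or `"csv"`.
#' @param channels optional channel filter (see [read_edf()]).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           channels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("edf", "rec")) "edf" else "csv"
  }
  switch(format,
    edf = read_edf(path, channels),
    csv = read_recording_csv(path, channels)
  )
}

#' Write a spindle annotation table as CSV
#'
#' @param annotations data frame with columns `subject_id`, `channel`,
#'   `onset_s`, `duration_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("subject_id", "channel", "onset_s",
                                   "duration_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a spindle annotation table
#'
#' Onsets are 0-based seconds from recording start; the event interval is
#' half-open `[onset, onset + duration)`. Rows with non-positive duration
#' are dropped with a warning stating how many were removed; malformed
#' numeric fields are an error naming the offending row.
#'
#' @param path CSV path with header
#'   `subject_id,channel,onset_s,duration_s`.
#' @return a validated annotation data frame (possibly with zero rows).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       channel = "character"))
  req <- c("subject_id", "channel", "onset_s", "duration_s")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stopf("annotation file missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_annotations())
  for (col in c("onset_s", "duration_s")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stopf("malformed numeric value in column '%s' at row %d", col, bad[1])
    }
    if (anyNA(v)) stopf("missing value in column '%s' at row %d", col,
                        which(is.na(v))[1])
    df[[col]] <- v
  }
  if (any(df$onset_s < 0)) {
    stopf("negative onset_s at row %d", which(df$onset_s < 0)[1])
  }
  n_bad <- sum(df$duration_s <= 0)
  if (n_bad > 0) {
    warnf("dropped %d annotation row(s) with non-positive duration", n_bad)
    df <- df[df$duration_s > 0, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, req]
}
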