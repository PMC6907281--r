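#' Construct an EEG recording object
#'
#' In-memory container for a validated 19-channel scalp EEG: a channels x
#' samples matrix in microvolts on a trauma-relative timebase.
#'
#' @param patient_id opaque patient identifier.
#' @param data numeric matrix, channels x samples, in microvolts; rows must
#'   follow [CHANNELS_1020] order.
#' @param sample_rate sampling frequency in Hz.
#' @param trauma_offset hours between the trauma and the start of the
#'   recording (non-negative).
#' @param channel_labels channel names; defaults to the canonical set.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(patient_id, data, sample_rate,
                          trauma_offset, channel_labels = CHANNELS_1020) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (nrow(data) != length(channel_labels))
    stop("data must have one row per channel label")
  if (!all(is.finite(data)))
    stop("EEG samples must all be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (trauma_offset < 0) stop("trauma_offset must be non-negative (recording cannot precede the trauma)")
  structure(
    list(patient_id = as.character(patient_id),
         channel_labels = channel_labels,
         sample_rate = sample_rate,
         data = data,
         trauma_offset = trauma_offset),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> patient %s: %d channels x %d samples @ %g Hz, %.2f h post-trauma (%.1f min)\n",
              x$patient_id, nrow(x$data), ncol(x$data), x$sample_rate,
              x$trauma_offset, ncol(x$data) / x$sample_rate / 60))
  invisible(x)
}

# Recording duration in hours.
recording_hours <- function(rec) ncol(rec$data) / rec$sample_rate / 3600

# Fixed-width left-padded ASCII field for an EDF header.
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Minimal standard EDF (16-bit) writer used by the synthetic-cohort
#' generator and the test fixtures: one data record per second, identical
#' physical scaling for all channels.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @param start_time POSIXct start of the recording (stamped into the EDF
#'   header); defaults to an arbitrary epoch plus the trauma offset so that
#'   round-tripping with `trauma_time = start_time - trauma_offset` works.
#' @param physical_range symmetric physical range in the stated unit;
#'   samples outside it are clipped.
#' @param physical_dimension unit string written to the header ("uV" or "mV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path,
                      start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
                        rec$trauma_offset * 3600,
                      physical_range = c(-2000, 2000),
                      physical_dimension = "uV") {
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf supports integer sample rates only")
  fs <- as.integer(round(fs))
  x <- rec$data
  if (physical_dimension == "mV") x <- x / 1000
  nch <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  if (n_rec < 1) stop("recording shorter than one data record (1 s)")
  x <- x[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- physical_range[1]; pmax_ <- physical_range[2]
  dmin <- -32768L; dmax <- 32767L
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- round((pmin(pmax(x, pmin_), pmax_) - pmin_) / gain) + dmin
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$patient_id, 80),
    edf_field("Startdate synthetic cEEG", 80),
    edf_field(format(start_time, "%d.%m.%y"), 8),
    edf_field(format(start_time, "%H.%M.%S"), 8),
    edf_field(256 + 256 * nch, 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(nch, 4)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels,
                 function(l) edf_field(paste("EEG", l), 16), ""), collapse = ""),
    paste(rep(edf_field("synthetic", 80), nch), collapse = ""),
    paste(rep(edf_field(physical_dimension, 8), nch), collapse = ""),
    paste(rep(edf_field(pmin_, 8), nch), collapse = ""),
    paste(rep(edf_field(pmax_, 8), nch), collapse = ""),
    paste(rep(edf_field(dmin, 8), nch), collapse = ""),
    paste(rep(edf_field(dmax, 8), nch), collapse = ""),
    paste(rep(edf_field("BP 0.1-70Hz", 80), nch), collapse = ""),
    paste(rep(edf_field(fs, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)

  # records on disk are [record][channel][sample]; dig is channels x samples
  arr <- array(dig, dim = c(nch, fs, n_rec))
  writeBin(as.integer(aperm(arr, c(2, 1, 3))), con, size = 2, endian = "little")
  invisible(path)
}

parse_edf_datetime <- function(date8, time8) {
  dd <- as.integer(substr(date8, 1, 2))
  mm <- as.integer(substr(date8, 4, 5))
  yy <- as.integer(substr(date8, 7, 8))
  year <- if (yy >= 85) 1900 + yy else 2000 + yy
  as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mm, dd,
                     gsub("\\.", ":", time8)), tz = "UTC")
}

#' Read an EDF recording
#'
#' Reads a standard (16-bit) EDF file, validates that the 19 electrodes of
#' the 10-20 system are all present (label matching is case-insensitive and
#' tolerant of "EEG " prefixes and reference suffixes), reorders channels to
#' canonical order, converts samples to microvolts, resamples to 256 Hz when
#' recorded at another rate, and computes the trauma-relative start offset.
#'
#' @param path EDF file.
#' @param trauma_time time of the trauma, POSIXct or ISO-8601 string (UTC);
#'   must not be after the recording start.
#' @return An [eeg_recording] at 256 Hz.
#' @export
read_edf <- function(path, trauma_time) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  if (is.character(trauma_time))
    trauma_time <- as.POSIXct(trauma_time, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256) stop("not a valid EDF file (truncated header): ", path)
  fld <- function(from, len) trimws(substr(fixed, from, from + len - 1))
  patient <- fld(9, 80)
  start <- parse_edf_datetime(fld(169, 8), fld(177, 8))
  if (is.na(start)) stop("not a valid EDF file (unparseable start date/time): ", path)
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  nch <- suppressWarnings(as.integer(fld(253, 4)))
  if (any(is.na(c(n_rec, rec_dur, nch))) || nch < 1)
    stop("not a valid EDF file (malformed header counts): ", path)

  sig_hdr <- readChar(con, 256 * nch, useBytes = TRUE)
  sfld <- function(block_offset, len, i)
    trimws(substr(sig_hdr, block_offset + (i - 1) * len + 1, block_offset + i * len))
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80, 8)) * nch
  labels   <- vapply(seq_len(nch), function(i) sfld(off[1], 16, i), "")
  dims     <- vapply(seq_len(nch), function(i) sfld(off[3], 8, i), "")
  pmins    <- as.numeric(vapply(seq_len(nch), function(i) sfld(off[4], 8, i), ""))
  pmaxs    <- as.numeric(vapply(seq_len(nch), function(i) sfld(off[5], 8, i), ""))
  dmins    <- as.numeric(vapply(seq_len(nch), function(i) sfld(off[6], 8, i), ""))
  dmaxs    <- as.numeric(vapply(seq_len(nch), function(i) sfld(off[7], 8, i), ""))
  spr      <- as.integer(vapply(seq_len(nch), function(i) sfld(off[9], 8, i), ""))

  canon <- vapply(labels, canonical_channel, "", USE.NAMES = FALSE)
  missing_ch <- setdiff(CHANNELS_1020, canon)
  extra <- labels[is.na(canon)]
  if (length(missing_ch) || anyDuplicated(stats::na.omit(canon)))
    stop("channel-set error: missing 10-20 channels [",
         paste(missing_ch, collapse = ", "), "]",
         if (length(extra)) paste0("; unrecognized labels [",
                                   paste(extra, collapse = ", "), "]") else "")
  if (trauma_time > start)
    stop("chronology error: trauma_time (", format(trauma_time),
         ") is after the recording start (", format(start), ")")
  if (length(unique(spr[!is.na(canon)])) != 1)
    stop("format error: EEG channels have differing sample rates")
  fs <- spr[which(!is.na(canon))[1]] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr))
    stop("format error: EDF data section shorter than the header declares")

  # split the interleaved records back into per-channel sample streams
  ends <- cumsum(spr); starts <- ends - spr + 1
  rec_len <- sum(spr)
  data <- matrix(0, nrow = 19, ncol = n_rec * spr[1])
  for (i in seq_len(nch)) {
    ci <- canon[i]
    if (is.na(ci)) next
    idx <- as.vector(outer(starts[i]:ends[i], (seq_len(n_rec) - 1) * rec_len, "+"))
    x <- raw[idx]
    gain <- (pmaxs[i] - pmins[i]) / (dmaxs[i] - dmins[i])
    phys <- (x - dmins[i]) * gain + pmins[i]
    unit <- tolower(dims[i])
    scale <- switch(unit, "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6, 1)
    data[match(ci, CHANNELS_1020), ] <- phys * scale
  }

  trauma_offset <- as.numeric(difftime(start, trauma_time, units = "hours"))
  rec <- eeg_recording(patient, data, fs, trauma_offset)
  if (abs(fs - 256) > 1e-9) rec <- resample_recording(rec, 256)
  rec
}

# Polyphase resampling of all channels to a new rate (integer rates only).
resample_recording <- function(rec, new_fs = 256) {
  p <- as.integer(new_fs); q <- as.integer(round(rec$sample_rate))
  if (abs(rec$sample_rate - q) > 1e-6)
    stop("format error: non-integer sample rate ", rec$sample_rate)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  out <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
  eeg_recording(rec$patient_id, out, new_fs, rec$trauma_offset,
                rec$channel_labels)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
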