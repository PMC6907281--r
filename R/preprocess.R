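#' Default preprocessing thresholds
#'
#' Artifact screening thresholds: absolute amplitude 150 microvolts, epoch
#' variance above 1400 uV^2 (noise/movement) or at/below 1 uV^2 (empty
#' channel), applied per 10-s epoch per channel in the common-average
#' reference.  `min_valid_channels` is the minimum number of clean
#' electrodes for an epoch to be used at all (global features such as the
#' symmetry index or coherence are meaningless on very sparse montages).
#'
#' @return Named list of thresholds.
#' @export
preprocess_config <- function(amp_uV = 150, var_hi_uV2 = 1400, var_lo_uV2 = 1,
                              min_valid_channels = 9) {
  list(amp_uV = amp_uV, var_hi_uV2 = var_hi_uV2, var_lo_uV2 = var_lo_uV2,
       min_valid_channels = min_valid_channels)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, 0.5-30 Hz: a
#' 3rd-order design applied in both directions realises the 6th-order
#' zero-phase magnitude response with no group delay.
#'
#' @param view a `montage_view` (any kind); at least 10 s of data.
#' @param low,high band edges in Hz.
#' @return The filtered `montage_view`, same shape.
#' @export
bandpass <- function(view, low = 0.5, high = 30) {
  stopifnot(inherits(view, "montage_view") || inherits(view, "analysis_window"))
  if (!all(is.finite(view$data))) stop("non-finite samples in input")
  fs <- view$sample_rate
  if (ncol(view$data) < 10 * fs) stop("window shorter than the 10-s filter warm-up")
  bf <- signal::butter(3, c(low, high) / (fs / 2), type = "pass")
  out <- view
  out$data <- filtfilt_rows(bf$b, bf$a, out$data, pad = round(10 * fs))
  out
}

# same zero-phase filter applied to the raw channels of a recording;
# montage derivations commute with the (linear) filter, so filtering the
# 19 channels once is equivalent to filtering each derived montage.
filter_recording <- function(rec, low = 0.5, high = 30) {
  bf <- signal::butter(3, c(low, high) / (rec$sample_rate / 2), type = "pass")
  rec$data <- filtfilt_rows(bf$b, bf$a, rec$data, pad = round(10 * rec$sample_rate))
  rec
}

#' Per-epoch channel artifact detection
#'
#' Screens a 10-min common-average window in 10-s epochs: a channel is
#' rejected in an epoch when any sample reaches +/-150 uV (`amplitude`),
#' when the epoch variance reaches 1400 uV^2 (`variance-high`), or when it
#' falls to 1 uV^2 or below (`empty`; a constant channel has variance 0).
#' Variance is the population variance of the mean-removed epoch.  Epochs
#' retaining fewer than `min_valid_channels` clean channels are dropped
#' wholly (recorded in `epoch_valid`, reasons untouched).
#'
#' @param ca_window an `analysis_window` in the common-average montage.
#' @param config see [preprocess_config()].
#' @return An `artifact_mask`: `valid` (epochs x channels logical),
#'   `reasons` (character, "" where valid), `epoch_valid` (length-60
#'   logical), `epoch_sec`, `min_valid_channels`.
#' @export
detect_artifacts <- function(ca_window, config = preprocess_config()) {
  stopifnot(inherits(ca_window, "analysis_window"),
            ca_window$kind == "common-average")
  fs <- ca_window$sample_rate
  ep_len <- round(10 * fs)
  n_ep <- floor(ncol(ca_window$data) / ep_len)
  nch <- nrow(ca_window$data)
  valid <- matrix(TRUE, n_ep, nch)
  reasons <- matrix("", n_ep, nch)
  for (e in seq_len(n_ep)) {
    seg <- ca_window$data[, ((e - 1) * ep_len + 1):(e * ep_len), drop = FALSE]
    amp_bad <- apply(abs(seg), 1, max) >= config$amp_uV
    mu <- rowMeans(seg)
    v <- rowMeans((seg - mu)^2)            # population variance
    hi <- v >= config$var_hi_uV2
    lo <- v <= config$var_lo_uV2
    reasons[e, lo] <- "empty"
    reasons[e, hi & !lo] <- "variance-high"
    reasons[e, amp_bad & !hi & !lo] <- "amplitude"
    valid[e, amp_bad | hi | lo] <- FALSE
  }
  colnames(valid) <- colnames(reasons) <- ca_window$derived_labels
  structure(
    list(valid = valid, reasons = reasons,
         epoch_valid = rowSums(valid) >= config$min_valid_channels,
         epoch_sec = 10, min_valid_channels = config$min_valid_channels),
    class = "artifact_mask")
}

#' Apply an electrode artifact mask to the bipolar window
#'
#' A bipolar derivation is excluded in an epoch when either of its two
#' source electrodes was rejected in that epoch (a contaminated electrode
#' corrupts every derivation it touches), or when the whole epoch was
#' dropped.  Sample values of retained derivations are never altered.
#'
#' @param bp_window an `analysis_window` in the longitudinal-bipolar
#'   montage, co-registered with the mask.
#' @param mask an `artifact_mask` from [detect_artifacts()] on the matching
#'   common-average window.
#' @param ca_window optional: the matching common-average window, carried
#'   along for electrode-resolved features (centre of gravity).
#' @return A `masked_window`: the bipolar window plus `deriv_valid`
#'   (epochs x derivations), `elec_valid`, `epoch_valid`, `usable`.
#' @export
apply_mask <- function(bp_window, mask, ca_window = NULL) {
  stopifnot(inherits(bp_window, "analysis_window"),
            bp_window$kind == "longitudinal-bipolar",
            inherits(mask, "artifact_mask"))
  li <- match(BIPOLAR_PAIRS[, 1], colnames(mask$valid))
  ri <- match(BIPOLAR_PAIRS[, 2], colnames(mask$valid))
  dv <- mask$valid[, li, drop = FALSE] & mask$valid[, ri, drop = FALSE]
  dv <- dv & mask$epoch_valid
  colnames(dv) <- BIPOLAR_LABELS
  structure(
    list(interval = bp_window$interval, window_index = bp_window$window_index,
         fallback_shift = bp_window$fallback_shift,
         data = bp_window$data, derived_labels = bp_window$derived_labels,
         sample_rate = bp_window$sample_rate,
         deriv_valid = dv,
         elec_valid = mask$valid & mask$epoch_valid,
         epoch_valid = mask$epoch_valid,
         ca_data = if (!is.null(ca_window)) ca_window$data else NULL,
         usable = any(dv)),
    class = "masked_window")
}

#' Per-window artifact report
#'
#' Long-format QC table of every rejected (epoch, channel) with its reason.
#'
#' @param mask an `artifact_mask`.
#' @return data.frame with columns epoch, channel, reason.
#' @export
artifact_report <- function(mask) {
  bad <- which(!mask$valid, arr.ind = TRUE)
  data.frame(epoch = bad[, 1],
             channel = colnames(mask$valid)[bad[, 2]],
             reason = mask$reasons[bad],
             stringsAsFactors = FALSE)
}
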