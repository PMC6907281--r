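#' Re-reference a recording to a derived montage
#'
#' Common average: each channel minus the instantaneous mean over all 19
#' channels.  Longitudinal bipolar: the 18 "double banana" derivations
#' (adjacent-electrode differences) in standard order.
#'
#' @param rec an [eeg_recording] (or a `montage_view`; views pass through
#'   unchanged when already of the requested kind).
#' @param kind `"common-average"` or `"longitudinal-bipolar"`.
#' @return A `montage_view`: list with `kind`, `derived_labels`, `data`
#'   (derivations x samples, microvolts) and `sample_rate`.
#' @export
to_montage <- function(rec, kind = c("common-average", "longitudinal-bipolar")) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  if (kind == "common-average") {
    out <- sweep(x, 2, colMeans(x))
    labels <- rec$channel_labels
  } else {
    li <- match(BIPOLAR_PAIRS[, 1], rec$channel_labels)
    ri <- match(BIPOLAR_PAIRS[, 2], rec$channel_labels)
    out <- x[li, , drop = FALSE] - x[ri, , drop = FALSE]
    labels <- BIPOLAR_LABELS
  }
  structure(list(kind = kind, derived_labels = labels, data = out,
                 sample_rate = rec$sample_rate),
            class = "montage_view")
}

#' @export
print.montage_view <- function(x, ...) {
  cat(sprintf("<montage_view:%s> %d derivations x %d samples @ %g Hz\n",
              x$kind, nrow(x$data), ncol(x$data), x$sample_rate))
  invisible(x)
}

# subset a montage view to a sample range, preserving metadata
view_slice <- function(view, from, to) {
  out <- view
  out$data <- view$data[, from:to, drop = FALSE]
  out
}

#' Slice trauma-relative analysis segments into 10-min windows
#'
#' For each requested post-trauma interval (24/48/72/96 h) selects the
#' 60-min segment starting at that hour and cuts it into six contiguous
#' 10-min windows.  When the nominal hour is not fully covered by the
#' recording, earlier and later complete hours are tried in the order
#' -1 h, +1 h, -2 h, +2 h and the shift actually used is recorded; an hour
#' qualifies only when fully covered.  Intervals with no usable hour are
#' reported in the `missing_intervals` attribute, not an error.
#'
#' @param view a full-recording `montage_view` (typically already
#'   band-pass filtered; filtering before slicing keeps filter edge
#'   transients out of the analysis windows).
#' @param rec the source [eeg_recording] (for the trauma offset/coverage).
#' @param intervals subset of `c(24, 48, 72, 96)` hours post-trauma.
#' @return List of `analysis_window` objects (fields `interval`,
#'   `window_index` 1-6, `fallback_shift`, `data`, `sample_rate`), with
#'   attribute `missing_intervals`.
#' @export
slice_windows <- function(view, rec, intervals = c(24, 48, 72, 96)) {
  stopifnot(all(intervals %in% c(24, 48, 72, 96)))
  fs <- view$sample_rate
  start_h <- rec$trauma_offset
  end_h <- rec$trauma_offset + ncol(view$data) / fs / 3600
  out <- list()
  missing <- numeric(0)
  for (iv in intervals) {
    shift <- NA_real_
    for (s in c(0, -1, 1, -2, 2)) {       # prefer earlier physiology on ties
      lo <- iv + s
      if (lo >= start_h - 1e-9 && lo + 1 <= end_h + 1e-9) { shift <- s; break }
    }
    if (is.na(shift)) { missing <- c(missing, iv); next }
    seg0 <- round((iv + shift - start_h) * 3600 * fs)
    for (w in 1:6) {
      from <- seg0 + (w - 1) * 600 * fs + 1
      to <- min(seg0 + w * 600 * fs, ncol(view$data))
      out[[length(out) + 1]] <- structure(
        list(interval = iv, window_index = w, fallback_shift = shift,
             data = view$data[, from:to, drop = FALSE],
             derived_labels = view$derived_labels,
             kind = view$kind, sample_rate = fs),
        class = "analysis_window")
    }
  }
  attr(out, "missing_intervals") <- missing
  out
}
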