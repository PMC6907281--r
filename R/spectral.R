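# Spectral estimation for 10-min analysis windows.
#
# All spectral features are computed from Welch periodograms of the 10-s
# epochs: 4-s Hamming-tapered segments with 50% overlap (0.25 Hz
# resolution, enough to resolve the 0.5 Hz lower band edge and consistent
# with the 4-s/50% settings used for coherence).

welch_segment_starts <- function(ep_len, seg_len, overlap = 0.5) {
  step <- round(seg_len * (1 - overlap))
  seq(1, ep_len - seg_len + 1, by = step)
}

# trapezoidal band integral over the closed interval [lo, hi]; `psd` has
# frequencies along rows.  The frequency grid is assumed to contain the
# band edges exactly (true for 0.25 Hz resolution and the clinical bands),
# so neighbouring bands share each edge's half-trapezoid and the four band
# integrals sum exactly to the integral over the total range.
band_integral <- function(psd, freqs, band) {
  sel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  f <- freqs[sel]
  w <- diff(f)
  wts <- c(w / 2, 0) + c(0, w / 2)
  if (is.matrix(psd)) as.vector(crossprod(psd[sel, , drop = FALSE], wts))
  else sum(psd[sel] * wts)
}

# tapered, demeaned Welch segments of every row of `x`, batched into one
# seg_len x (n_segments * n_rows) matrix for a single mvfft call; returns
# the one-sided squared spectra, truncated at `nf_keep` bins, as an array
# (nf_keep, n_segments, n_rows).
batched_segment_power <- function(x, starts, seg_len, taper, fs, nf_keep) {
  nr <- nrow(x)
  ns <- length(starts)
  nf <- seg_len %/% 2 + 1
  segs <- segment_matrix(x, as.integer(starts), seg_len, taper)
  F1 <- stats::mvfft(segs)[seq_len(nf_keep), , drop = FALSE]
  P <- (Re(F1)^2 + Im(F1)^2) / (fs * sum(taper^2))
  one <- 2:min(nf_keep, nf - 1)
  P[one, ] <- 2 * P[one, ]   # one-sided
  dim(P) <- c(nf_keep, ns, nr)
  P
}

#' Welch power spectral density of a masked window
#'
#' Per valid 10-s epoch and derivation, the Welch estimate with 4-s
#' Hamming-tapered segments at 50% overlap; the window-level PSD averages
#' over the valid epochs.  Per-epoch band powers (derivation-averaged
#' within each epoch) are retained for the variability features.
#'
#' @param mw a `masked_window` from [apply_mask()].
#' @param seg_sec Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @param fmax truncate the returned spectrum above this frequency (Hz;
#'   NULL keeps the full grid up to Nyquist).  All features live below
#'   20 Hz and the signal is filtered at 30 Hz, so the default loses
#'   nothing.
#' @return A `spectral_estimate`: `freqs` (Hz), `psd` (derivations x
#'   frequencies, uV^2/Hz, each derivation averaged over its valid epochs;
#'   NA rows where a derivation has none), `epoch_band_powers` (epochs x 4
#'   bands, NA rows for dropped epochs), `n_valid_epochs`.
#' @export
welch_psd <- function(mw, seg_sec = 4, overlap = 0.5, fmax = 30) {
  stopifnot(inherits(mw, "masked_window"))
  if (!any(mw$deriv_valid)) stop("unusable window: no valid epochs")
  fs <- mw$sample_rate
  ep_len <- round(10 * fs)
  n_ep <- nrow(mw$deriv_valid)
  nd <- nrow(mw$data)
  seg_len <- round(seg_sec * fs)
  ep_starts <- welch_segment_starts(ep_len, seg_len, overlap)
  n_per_ep <- length(ep_starts)
  taper <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  nf_full <- seg_len %/% 2 + 1
  freqs_full <- (seq_len(nf_full) - 1) * fs / seg_len
  nf <- if (is.null(fmax)) nf_full else max(which(freqs_full <= fmax + 1e-9))
  freqs <- freqs_full[seq_len(nf)]
  starts <- as.vector(outer(ep_starts, (seq_len(n_ep) - 1) * ep_len, "+"))

  P <- batched_segment_power(mw$data, starts, seg_len, taper, fs, nf)
  dim(P) <- c(nf, n_per_ep, n_ep, nd)
  pe <- colMeans(aperm(P, c(2, 1, 3, 4)))          # (nf, n_ep, nd)
  for (d in seq_len(nd)) pe[, !mw$deriv_valid[, d], d] <- NA_real_

  psd <- t(vapply(seq_len(nd),
                  function(d) rowMeans(pe[, , d, drop = FALSE], na.rm = TRUE),
                  numeric(nf)))
  psd[colSums(mw$deriv_valid) == 0, ] <- NA_real_
  rownames(psd) <- mw$derived_labels

  # per-epoch band powers: derivation-averaged within the epoch
  bands <- band_scheme()[c("delta", "theta", "alpha", "beta")]
  epoch_psd <- rowMeans(pe, dims = 2, na.rm = TRUE)  # (nf, n_ep)
  ebp <- matrix(NA_real_, n_ep, 4, dimnames = list(NULL, names(bands)))
  have <- colSums(!is.na(epoch_psd)) > 0
  for (b in seq_along(bands))
    ebp[have, b] <- band_integral(epoch_psd[, have, drop = FALSE],
                                  freqs, bands[[b]])
  structure(list(freqs = freqs, psd = psd, epoch_band_powers = ebp,
                 n_valid_epochs = sum(rowSums(mw$deriv_valid) > 0)),
            class = "spectral_estimate")
}

# Welch PSD on arbitrary (channels x samples) data with an epochs x
# channels validity mask -- used for electrode-resolved power (centre of
# gravity) on the common-average montage.  Returns channels x nf PSD.
welch_psd_matrix <- function(x, valid, fs, seg_sec = 4, overlap = 0.5, fmax = 20) {
  ep_len <- round(10 * fs)
  n_ep <- nrow(valid)
  seg_len <- round(seg_sec * fs)
  ep_starts <- welch_segment_starts(ep_len, seg_len, overlap)
  taper <- 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  nf_full <- seg_len %/% 2 + 1
  freqs_full <- (seq_len(nf_full) - 1) * fs / seg_len
  nf <- if (is.null(fmax)) nf_full else max(which(freqs_full <= fmax + 1e-9))
  starts <- as.vector(outer(ep_starts, (seq_len(n_ep) - 1) * ep_len, "+"))
  P <- batched_segment_power(x, starts, seg_len, taper, fs, nf)
  dim(P) <- c(nf, length(ep_starts), n_ep, nrow(x))
  out <- matrix(NA_real_, nrow(x), nf)
  for (d in seq_len(nrow(x))) {
    if (!any(valid[, d])) next
    out[d, ] <- rowMeans(P[, , valid[, d], d, drop = FALSE], dims = 1)
  }
  list(freqs = freqs_full[seq_len(nf)], psd = out)
}

#' Mean magnitude-squared coherence
#'
#' Mean magnitude-squared coherence over all unordered derivation pairs,
#' estimated on the full 10 min of valid data per pair with 4-s Hanning
#' segments and 2-s overlap, averaged over 0.5-20 Hz.  A segment enters a
#' pair's estimate only when it lies entirely in epochs valid for both
#' derivations.
#'
#' @param mw a `masked_window`.
#' @param band frequency range (Hz) over which MSC is averaged.
#' @return Scalar in `[0, 1]`, or NA when fewer than two derivations are
#'   valid.
#' @export
coherence <- function(mw, band = c(0.5, 20)) {
  stopifnot(inherits(mw, "masked_window"))
  fs <- mw$sample_rate
  seg_len <- round(4 * fs)
  step <- round(2 * fs)
  n <- ncol(mw$data)
  starts <- seq(1, n - seg_len + 1, by = step)
  ep_len <- round(10 * fs)
  nd <- nrow(mw$data)
  if (sum(colSums(mw$deriv_valid) > 0) < 2) return(NA_real_)

  # a segment is valid for a derivation when both epochs it touches are
  ep_first <- (starts - 1) %/% ep_len + 1
  ep_last <- (starts + seg_len - 2) %/% ep_len + 1
  ev <- rbind(mw$deriv_valid, FALSE)
  seg_ok <- ev[ep_first, , drop = FALSE] &
    ev[pmin(ep_last, nrow(ev)), , drop = FALSE]

  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  nf <- seg_len %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / seg_len
  fsel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  ns <- length(starts)
  segs <- segment_matrix(mw$data, as.integer(starts), seg_len, taper)
  F1 <- stats::mvfft(segs)[fsel, , drop = FALSE]
  res <- msc_mean_pairs(as.numeric(Re(F1)), as.numeric(Im(F1)),
                        matrix(as.integer(seg_ok), ns, nd),
                        length(fsel), ns, nd)
  as.numeric(res)
}
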