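# The 23 quantitative EEG features per 10-min window.

#' Names of the 23 qEEG features, in fixed order
#' @export
QEEG_FEATURE_NAMES <- c(
  "abs_delta", "abs_theta", "abs_alpha", "abs_beta", "total_power",
  "rel_delta", "rel_theta", "rel_alpha", "rel_beta",
  "adr", "sef90",
  "var_delta", "var_theta", "var_alpha", "var_beta",
  "bsi_total", "bsi_delta",
  "cog_x", "cog_y",
  "mean_amplitude", "coherence", "shannon_entropy", "regularity"
)

#' Absolute, total and relative band powers
#'
#' Absolute power per band is the trapezoidal integral of the PSD over the
#' band, averaged across derivations; total power is the sum of the four
#' band powers (0.5-20 Hz); relative power is the band/total ratio.
#'
#' @param spec a `spectral_estimate` from [welch_psd()].
#' @param scheme a [band_scheme()].
#' @return List with `abs` (named length 4), `total`, `rel` (named, sums
#'   to 1).
#' @export
band_powers <- function(spec, scheme = band_scheme()) {
  ok <- rowSums(!is.na(spec$psd)) > 0
  if (!any(ok)) stop("degenerate spectrum: no derivation carries power")
  psd <- t(spec$psd[ok, , drop = FALSE])      # freqs x derivations
  bands <- scheme[c("delta", "theta", "alpha", "beta")]
  per_der <- vapply(bands, function(b) band_integral(psd, spec$freqs, b),
                    numeric(ncol(psd)))
  if (is.null(dim(per_der))) per_der <- matrix(per_der, nrow = 1)
  abs_p <- colMeans(per_der)
  total <- sum(abs_p)
  if (total <= 0) stop("degenerate spectrum: zero total power")
  list(abs = abs_p, total = total, rel = abs_p / total)
}

#' Alpha/delta power ratio
#' @param powers output of [band_powers()].
#' @return alpha power / delta power; NA when delta power is zero.
#' @export
adr <- function(powers) {
  if (powers$abs[["delta"]] <= 0) return(NA_real_)
  powers$abs[["alpha"]] / powers$abs[["delta"]]
}

#' Spectral edge frequency (90%)
#'
#' The smallest frequency in the total-power range (0.5-20 Hz) below which
#' 90% of the derivation-averaged power lies, with linear interpolation
#' between grid points.
#'
#' @param spec a `spectral_estimate`.
#' @return Frequency in Hz.
#' @export
sef90 <- function(spec, band = c(0.5, 20), q = 0.9) {
  ok <- rowSums(!is.na(spec$psd)) > 0
  p <- colMeans(spec$psd[ok, , drop = FALSE])
  sel <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  f <- spec$freqs[sel]; p <- p[sel]
  cum <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(f)))
  tot <- cum[length(cum)]
  if (tot <= 0) return(NA_real_)
  target <- q * tot
  i <- which(cum >= target)[1]
  if (i == 1) return(f[1])
  f[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
}

#' Band-power variability
#'
#' Per band, the ratio of the median absolute deviation to the median of
#' the 60 per-epoch band powers, clipped to `[0, 1]`.  Requires at least 8
#' valid epochs for a stable median; the MAD is unscaled (no normal
#' consistency constant) so the ratio lives on the documented 0-1 range.
#'
#' @param spec a `spectral_estimate`.
#' @return Named numeric length 4 (delta/theta/alpha/beta), NA where
#'   undefined.
#' @export
variability <- function(spec, min_epochs = 8) {
  vapply(colnames(spec$epoch_band_powers), function(b) {
    x <- spec$epoch_band_powers[, b]
    x <- x[!is.na(x)]
    if (length(x) < min_epochs) return(NA_real_)
    m <- stats::median(x)
    if (m <= 0) return(NA_real_)
    min(1, stats::mad(x, constant = 1) / m)
  }, numeric(1))
}

#' Pairwise brain symmetry index
#'
#' For each homologous left/right bipolar derivation pair and each
#' frequency in the range, the normalised spectral difference
#' `|(R - L) / (R + L)|`, averaged over pairs and frequencies; 0 for a
#' perfectly symmetric EEG, towards 1 for a one-sided EEG.  Midline
#' derivations have no mirror and are excluded.  Computed for the total
#' range (0.5-20 Hz) and the delta band (0.5-4 Hz).
#'
#' @param spec a `spectral_estimate` on the bipolar montage.
#' @return Named numeric: `bsi_total`, `bsi_delta`; NA when no homologous
#'   pair is valid.
#' @export
bsi <- function(spec, scheme = band_scheme()) {
  out <- c(bsi_total = NA_real_, bsi_delta = NA_real_)
  ranges <- list(bsi_total = scheme$total, bsi_delta = scheme$delta)
  for (k in names(ranges)) {
    rg <- ranges[[k]]
    fsel <- which(spec$freqs >= rg[1] - 1e-9 & spec$freqs <= rg[2] + 1e-9)
    vals <- numeric(0)
    for (p in seq_len(nrow(BSI_PAIRS))) {
      L <- spec$psd[BSI_PAIRS[p, "left"], fsel]
      R <- spec$psd[BSI_PAIRS[p, "right"], fsel]
      if (all(is.na(L)) || all(is.na(R))) next
      s <- R + L
      vals <- c(vals, abs(R - L)[s > 0] / s[s > 0])
    }
    if (length(vals)) out[k] <- mean(vals)
  }
  out
}

#' Centre of gravity of the power topography
#'
#' Power-weighted centroid of the electrode positions: per-electrode total
#' (0.5-20 Hz) power is estimated from the common-average montage (bipolar
#' derivations do not resolve single electrodes) and combined with the
#' unit-disc 10-20 coordinate table; x runs -1 (left) to +1 (right), y -1
#' (posterior) to +1 (anterior).
#'
#' @param mw a `masked_window` carrying the common-average data.
#' @param coords coordinate table, see [electrode_coordinates()].
#' @return Named numeric `cog_x`, `cog_y` in `[-1, 1]`; NA when fewer than
#'   half the electrodes carry valid power.
#' @export
cog <- function(mw, coords = electrode_coordinates(), scheme = band_scheme()) {
  if (is.null(mw$ca_data)) return(c(cog_x = NA_real_, cog_y = NA_real_))
  if (sum(colSums(mw$elec_valid) > 0) < ceiling(ncol(mw$elec_valid) / 2))
    return(c(cog_x = NA_real_, cog_y = NA_real_))
  w <- welch_psd_matrix(mw$ca_data, mw$elec_valid, mw$sample_rate)
  P <- band_integral(t(w$psd), w$freqs, scheme$total)
  P[is.na(P)] <- 0
  if (sum(P) <= 0) return(c(cog_x = NA_real_, cog_y = NA_real_))
  c(cog_x = sum(coords$x * P) / sum(P),
    cog_y = sum(coords$y * P) / sum(P))
}

#' Mean amplitude
#'
#' The standard deviation of the signal: computed per derivation per valid
#' 10-s epoch and averaged over derivations and epochs, in microvolts.
#'
#' @param mw a `masked_window`.
#' @return Microvolts.
#' @export
mean_amplitude <- function(mw) {
  ep_len <- round(10 * mw$sample_rate)
  n_ep <- nrow(mw$deriv_valid)
  sds <- epoch_sd(mw$data, ep_len, n_ep)      # epochs x derivations
  sds[!mw$deriv_valid] <- NA_real_
  if (all(is.na(sds))) return(NA_real_)
  mean(sds, na.rm = TRUE)
}

#' Shannon entropy of the amplitude distribution
#'
#' Per derivation, the Shannon entropy (bits) of the histogram of sample
#' amplitudes over the valid epochs, with 100 equal-width bins spanning
#' the artifact-clean range -150..+150 uV (samples outside are counted in
#' the edge bins); averaged over derivations.  0 for a constant signal,
#' log2(100) ~ 6.64 bits for a uniform one.
#'
#' @param mw a `masked_window`.
#' @param n_bins number of histogram bins.
#' @param range amplitude range spanned by the bins, microvolts.
#' @return Bits.
#' @export
shannon_entropy <- function(mw, n_bins = 100, range = c(-150, 150)) {
  fs <- mw$sample_rate
  ep_len <- round(10 * fs)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  H <- numeric(0)
  for (d in seq_len(nrow(mw$data))) {
    eps <- which(mw$deriv_valid[, d])
    if (!length(eps)) next
    idx <- as.vector(outer(seq_len(ep_len), (eps - 1) * ep_len, "+"))
    x <- pmin(pmax(mw$data[d, idx], range[1]), range[2] - 1e-9)
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = n_bins)
    p <- cnt[cnt > 0] / sum(cnt)
    H <- c(H, -sum(p * log2(p)))
  }
  if (!length(H)) return(NA_real_)
  mean(H)
}

#' Regularity of the EEG amplitude
#'
#' Continuity measure on the squared, 0.5-s moving-average-smoothed signal:
#' with the smoothed values sorted descending as q_1 >= ... >= q_N,
#' `REG = sqrt( sum(i^2 q_i) / ((N^2/3) sum(q_i)) )`, computed per
#' derivation per valid epoch and averaged, clipped to `[0, 1]`.  A
#' constant-amplitude signal gives values near 1; a burst-suppression-like
#' signal, where the amplitude is concentrated in a small fraction of the
#' time, gives low values.
#'
#' @param mw a `masked_window`.
#' @param smooth_sec moving-average length in seconds.
#' @return Value in `[0, 1]`.
#' @export
regularity <- function(mw, smooth_sec = 0.5) {
  fs <- mw$sample_rate
  ep_len <- round(10 * fs)
  n_ep <- nrow(mw$deriv_valid)
  k <- round(smooth_sec * fs)
  Ns <- ep_len - k + 1
  i2 <- seq_len(Ns)^2
  vals <- numeric(0)
  for (d in seq_len(nrow(mw$data))) {
    eps <- which(mw$deriv_valid[, d])
    if (!length(eps)) next
    m <- matrix(mw$data[d, seq_len(n_ep * ep_len)]^2,
                nrow = ep_len)[, eps, drop = FALSE]
    cs <- apply(m, 2, cumsum)
    sm <- (cs[k:ep_len, , drop = FALSE] -
             rbind(0, cs[seq_len(ep_len - k), , drop = FALSE])) / k
    q <- apply(sm, 2, sort, decreasing = TRUE)
    tot <- colSums(q)
    reg <- sqrt(colSums(q * i2) / (Ns^2 / 3 * tot))
    vals <- c(vals, pmin(1, reg[tot > 0]))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Extract the 23 qEEG features from a 10-min window
#'
#' Assembles the full feature vector for one masked window.  Features that
#' cannot be computed (zero delta power, too few valid epochs, no valid
#' homologous pair, ...) are returned as NA; a window with no valid epochs
#' at all yields NULL.
#'
#' @param mw a `masked_window` from [apply_mask()].
#' @param scheme a [band_scheme()].
#' @param coords electrode coordinate table for the centre of gravity.
#' @return Named numeric vector of length 23 ([QEEG_FEATURE_NAMES]), or
#'   NULL for an unusable window.
#' @export
extract_features <- function(mw, scheme = band_scheme(),
                             coords = electrode_coordinates()) {
  stopifnot(inherits(mw, "masked_window"))
  if (!isTRUE(mw$usable)) return(NULL)
  spec <- welch_psd(mw)
  pw <- band_powers(spec, scheme)
  vb <- variability(spec)
  bs <- bsi(spec, scheme)
  cg <- cog(mw, coords, scheme)
  out <- c(
    abs_delta = pw$abs[["delta"]], abs_theta = pw$abs[["theta"]],
    abs_alpha = pw$abs[["alpha"]], abs_beta = pw$abs[["beta"]],
    total_power = pw$total,
    rel_delta = pw$rel[["delta"]], rel_theta = pw$rel[["theta"]],
    rel_alpha = pw$rel[["alpha"]], rel_beta = pw$rel[["beta"]],
    adr = adr(pw), sef90 = sef90(spec, scheme$total),
    var_delta = vb[["delta"]], var_theta = vb[["theta"]],
    var_alpha = vb[["alpha"]], var_beta = vb[["beta"]],
    bsi_total = bs[["bsi_total"]], bsi_delta = bs[["bsi_delta"]],
    cog_x = cg[["cog_x"]], cog_y = cg[["cog_y"]],
    mean_amplitude = mean_amplitude(mw),
    coherence = coherence(mw, scheme$total),
    shannon_entropy = shannon_entropy(mw),
    regularity = regularity(mw)
  )
  out[QEEG_FEATURE_NAMES]
}

#' Full per-recording feature table
#'
#' Runs the whole extraction chain on one recording: common-average and
#' longitudinal-bipolar montages, 0.5-30 Hz zero-phase filtering of each
#' 60-min segment, slicing into six 10-min windows per interval, artifact
#' screening in common average, masking of the bipolar derivations, and
#' feature extraction.
#'
#' @param rec an [eeg_recording].
#' @param intervals post-trauma hours to analyse.
#' @param config preprocessing thresholds, see [preprocess_config()].
#' @return data.frame: one row per usable window with `patient_id`,
#'   `interval`, `window_index`, `fallback_shift`, `n_valid_epochs`, and
#'   the 23 feature columns.
#' @export
recording_features <- function(rec, intervals = c(24, 48, 72, 96),
                               config = preprocess_config()) {
  # filtering is linear, so filtering the 19 channels once is equivalent
  # to filtering each derived montage; done per 60-min segment, before
  # slicing, to keep filter edge transients out of the analysis windows
  rec_f <- filter_recording(rec)
  ca <- to_montage(rec_f, "common-average")
  bp <- to_montage(rec_f, "longitudinal-bipolar")
  ca_w <- slice_windows(ca, rec, intervals)
  bp_w <- slice_windows(bp, rec, intervals)
  rows <- list()
  for (i in seq_along(ca_w)) {
    mask <- detect_artifacts(ca_w[[i]], config)
    mw <- apply_mask(bp_w[[i]], mask, ca_w[[i]])
    fv <- extract_features(mw)
    if (is.null(fv)) next
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = rec$patient_id,
      interval = mw$interval, window_index = mw$window_index,
      fallback_shift = mw$fallback_shift,
      n_valid_epochs = sum(rowSums(mw$deriv_valid) > 0),
      t(fv), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(), interval = numeric(),
                      window_index = integer(), fallback_shift = numeric(),
                      n_valid_epochs = integer())
  attr(out, "missing_intervals") <- attr(ca_w, "missing_intervals")
  out
}
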