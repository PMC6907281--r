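# Fixture builders and independent oracles, all generated in code.

FS <- 256
EPOCH_LEN <- 10 * FS

# recording filled from a channels x samples matrix (canonical order)
make_recording <- function(data, fs = FS, trauma_offset = 24, id = "P001") {
  eeg_recording(id, data, fs, trauma_offset)
}

# analysis_window built directly from a derivations x samples matrix
make_window <- function(data, kind = "longitudinal-bipolar", fs = FS,
                        labels = NULL) {
  if (is.null(labels))
    labels <- if (kind == "longitudinal-bipolar") BIPOLAR_LABELS else CHANNELS_1020
  structure(list(interval = 24, window_index = 1, fallback_shift = 0,
                 data = data, derived_labels = labels, kind = kind,
                 sample_rate = fs),
            class = "analysis_window")
}

# masked_window with an all-valid mask, built directly from bipolar data
# (and optional common-average data for the centre of gravity)
make_masked <- function(bp_data, ca_data = NULL, fs = FS) {
  n_ep <- floor(ncol(bp_data) / (10 * fs))
  dv <- matrix(TRUE, n_ep, nrow(bp_data),
               dimnames = list(NULL, BIPOLAR_LABELS[seq_len(nrow(bp_data))]))
  ev <- matrix(TRUE, n_ep, 19, dimnames = list(NULL, CHANNELS_1020))
  structure(list(interval = 24, window_index = 1, fallback_shift = 0,
                 data = bp_data, derived_labels = colnames(dv),
                 sample_rate = fs, deriv_valid = dv, elec_valid = ev,
                 epoch_valid = rep(TRUE, n_ep), ca_data = ca_data,
                 usable = TRUE),
            class = "masked_window")
}

# sinusoid in microvolts
tone <- function(freq, n, amp = 1, fs = FS, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(n) / fs + phase)
}

# 18-derivation window of independent band-limited noise plus optional
# tones; deterministic given seed
noise_bp_matrix <- function(n, nd = 18, sd = 20, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nd * n, sd = sd), nd, n)
}

# ---- independent brute-force periodogram oracle -------------------------
# One Hann-tapered periodogram per full 10-s epoch (no Welch segmentation
# or overlap; 0.1 Hz resolution), averaged over epochs and derivations.
# The taper keeps the oracle's own sidelobe leakage from polluting quiet
# bands when strong tones are present elsewhere in the spectrum.
oracle_psd <- function(x, fs = FS) {
  n_ep <- floor(ncol(x) / (10 * fs))
  N <- 10 * fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, N - 1) / (N - 1))
  acc <- NULL
  for (d in seq_len(nrow(x))) for (e in seq_len(n_ep)) {
    seg <- x[d, ((e - 1) * N + 1):(e * N)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (fs * sum(w^2))
    P <- P[1:(N / 2 + 1)]
    P[2:(N / 2)] <- 2 * P[2:(N / 2)]
    acc <- if (is.null(acc)) P else acc + P
  }
  list(freqs = (0:(N / 2)) * fs / N, psd = acc / (nrow(x) * n_ep))
}

oracle_band_power <- function(op, band) {
  sel <- op$freqs >= band[1] - 1e-9 & op$freqs <= band[2] + 1e-9
  f <- op$freqs[sel]; p <- op$psd[sel]
  sum((p[-1] + p[-length(p)]) / 2 * diff(f))
}

oracle_sef90 <- function(op, band = c(0.5, 20), q = 0.9) {
  sel <- op$freqs >= band[1] - 1e-9 & op$freqs <= band[2] + 1e-9
  f <- op$freqs[sel]; p <- op$psd[sel]
  cum <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(f)))
  target <- q * cum[length(cum)]
  i <- which(cum >= target)[1]
  f[i - 1] + (target - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
}

# ---- feature-level cohort (for model-stage tests) -----------------------
# Per-window feature rows drawn from outcome-conditioned distributions
# (no EEG synthesis); group means mirror the directions the EEG generator
# produces.  Used where only the modelling machinery is under test.
make_feature_cohort <- function(n_poor = 10, n_good = 10,
                                intervals = c(24, 48, 72, 96), seed = 1,
                                effect = TRUE) {
  spec <- if (effect)
    cohort_spec(n_poor = n_poor, n_good = n_good, seed = seed)
  else
    null_cohort_spec(n_poor = n_poor, n_good = n_good, seed = seed)
  clin <- simulate_clinical(spec)
  base <- c(abs_delta = 300, abs_theta = 120, abs_alpha = 250, abs_beta = 40,
            total_power = 710, rel_delta = 0.42, rel_theta = 0.17,
            rel_alpha = 0.35, rel_beta = 0.06, adr = 0.8, sef90 = 12,
            var_delta = 0.35, var_theta = 0.35, var_alpha = 0.38,
            var_beta = 0.4, bsi_total = 0.05, bsi_delta = 0.05,
            cog_x = 0, cog_y = 0, mean_amplitude = 27, coherence = 0.03,
            shannon_entropy = 5.2, regularity = 0.84)
  shift <- c(mean_amplitude = -15, total_power = -500, abs_alpha = -230,
             rel_alpha = -0.25, rel_delta = 0.2, adr = -0.7, sef90 = -5,
             bsi_total = 0.3, bsi_delta = 0.3, var_alpha = -0.25,
             shannon_entropy = -1.5)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(clin$clinical))) {
    poor <- clin$clinical$outcome[i] == "poor"
    for (iv in intervals) for (w in 1:6) {
      v <- base
      if (effect && poor) v[names(shift)] <- v[names(shift)] + shift
      v <- v + rnorm(length(v), 0, abs(base) * 0.08 + 0.01)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = clin$clinical$patient_id[i], interval = iv,
        window_index = w, fallback_shift = 0, n_valid_epochs = 60,
        t(v), stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, rows), clinical = clin$clinical,
       map = clin$map)
}

# ---- cached EEG-level cohorts (expensive; built once per test run) ------
.cohort_cache <- new.env(parent = emptyenv())

# strong-effect cohort at the default generator settings, 72 + 96 h
strong_eeg_cohort <- function() {
  if (is.null(.cohort_cache$strong)) {
    spec <- cohort_spec(n_poor = 6, n_good = 6, seed = 11)
    .cohort_cache$strong <- simulate_cohort_features(spec, intervals = c(72, 96))
  }
  .cohort_cache$strong
}

# null cohort (label-exchangeable), 40 patients, 72 h only
null_eeg_cohort <- function() {
  if (is.null(.cohort_cache$null)) {
    spec <- null_cohort_spec(n_poor = 20, n_good = 20, seed = 13)
    .cohort_cache$null <- simulate_cohort_features(spec, intervals = 72)
  }
  .cohort_cache$null
}
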