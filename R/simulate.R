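# Outcome-conditioned synthetic EEG cohorts.
#
# Signals are band-limited Gaussian processes (spectrally shaped noise)
# plus a 1/f background: the spectral quantities the features measure are
# then under exact control.  Poor outcome is emulated by global amplitude
# reduction, additional alpha suppression, right-hemisphere attenuation
# (asymmetry), reduced epoch-to-epoch amplitude modulation, older age and
# higher admission glucose; artifacts (flat epochs, high-amplitude
# transients) are injected at a configurable rate.

#' Synthetic cohort specification
#'
#' Generative parameters for an outcome-conditioned cohort.  Defaults give
#' a strongly separable cohort: poor-outcome EEG at half the overall
#' amplitude, alpha power additionally suppressed to 0.3x, right
#' hemisphere attenuated to 0.6x, epochwise amplitude modulation depth
#' 0.1 (vs 0.4 in good outcome), ~1 artifact epoch per 10-min window;
#' ages N(58, 12) poor vs N(38, 14) good (truncated at 18), admission
#' glucose shifted +2 mmol/L and MAP 10 mmHg lower in the poor group.
#'
#' @param n_poor,n_good patient counts per outcome group.
#' @param seed base RNG seed; all patient-level seeds derive from it.
#' @param amplitude_ratio overall poor/good EEG amplitude scale.
#' @param alpha_suppression extra multiplier on the poor group's
#'   alpha-band amplitude.
#' @param asymmetry_poor,asymmetry_good right-hemisphere amplitude gain.
#' @param variability_poor,variability_good epochwise amplitude-modulation
#'   depth (multiplier uniform in 1 +/- depth).
#' @param artifact_rate expected artifact epochs per 10-min window.
#' @param patient_scale_sd log-sd of the per-patient overall amplitude
#'   heterogeneity (same in both groups).
#' @param patient_band_sd log-sd of the per-patient per-band composition
#'   heterogeneity (same in both groups).
#' @param age_poor,age_good c(mean, sd) of age, truncated at 18 y.
#' @param glucose_shift added to the poor group's admission glucose, mmol/L.
#' @param map_poor,map_good c(mean, sd) of the patient-level MAP, mmHg.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_poor = 20, n_good = 20, seed = 1,
                        amplitude_ratio = 0.5, alpha_suppression = 0.3,
                        asymmetry_poor = 0.6, asymmetry_good = 1.0,
                        variability_poor = 0.1, variability_good = 0.4,
                        artifact_rate = 1,
                        patient_scale_sd = 0.20, patient_band_sd = 1.2,
                        age_poor = c(58, 12), age_good = c(38, 14),
                        glucose_shift = 2.0,
                        map_poor = c(80, 8), map_good = c(90, 8)) {
  stopifnot(n_poor >= 1, n_good >= 1, amplitude_ratio > 0,
            alpha_suppression > 0, asymmetry_poor > 0, asymmetry_good > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Neutralized (null) cohort specification
#'
#' Same generative process for both outcome groups: every
#' outcome-conditioned parameter is equalised, so the labels are
#' exchangeable.  Used for type-I-error / AUC-calibration experiments.
#'
#' @param ... passed to [cohort_spec()] (e.g. `n_poor`, `n_good`, `seed`).
#' @return A `cohort_spec` with attribute `neutralized` listing the
#'   equalised parameters.
#' @export
null_cohort_spec <- function(...) {
  spec <- cohort_spec(...,
                      amplitude_ratio = 1, alpha_suppression = 1,
                      asymmetry_poor = 1, asymmetry_good = 1,
                      variability_poor = 0.25, variability_good = 0.25,
                      age_poor = c(48, 14), age_good = c(48, 14),
                      glucose_shift = 0,
                      map_poor = c(85, 8), map_good = c(85, 8))
  attr(spec, "neutralized") <- c("amplitude_ratio", "alpha_suppression",
                                 "asymmetry", "variability", "age",
                                 "glucose_shift", "map")
  spec
}

# deterministic per-(patient, purpose) seed below 2^31
derive_seed <- function(seed, patient_idx, salt = 0) {
  as.integer((as.numeric(seed) * 100003 + patient_idx * 1009 + salt * 7) %% 2147483647)
}

# good-outcome group-mean band amplitudes (uV, sd per component)
BASE_BAND_SD <- c(delta = 8, theta = 4.5, alpha = 7.5, beta = 2.5)
BASE_FLOOR_SD <- 3.5   # 1/f background, 0.5-45 Hz
MAX_CHANNEL_SD <- 20   # cap keeping modulated amplitudes clear of 150 uV

# band amplitude profile for one patient: group means scaled by the
# outcome effects, then patient-level lognormal heterogeneity (overall
# scale and band composition; identical distribution in both groups, so
# null cohorts stay exchangeable).  Without the heterogeneity every
# spectral feature would separate the groups perfectly and importance
# rankings would be arbitrary.
outcome_band_sd <- function(spec, outcome, scale_jit = 1,
                            band_jit = rep(1, 4)) {
  s <- BASE_BAND_SD
  fl <- BASE_FLOOR_SD
  if (outcome == "poor") {
    s <- s * spec$amplitude_ratio
    s["alpha"] <- s["alpha"] * spec$alpha_suppression
    fl <- fl * spec$amplitude_ratio
  }
  # composition jitter is variance-preserving: it reshuffles power across
  # bands but leaves the patient's total power untouched, so the overall
  # amplitude effect is carried by scale_jit alone
  s2 <- sum(s^2)
  s <- s * band_jit
  s <- s * sqrt(s2 / sum(s^2))
  s <- s * scale_jit
  fl <- fl * scale_jit
  tot <- sqrt(sum(s^2) + fl^2)
  if (tot > MAX_CHANNEL_SD) {
    s <- s * MAX_CHANNEL_SD / tot
    fl <- fl * MAX_CHANNEL_SD / tot
  }
  list(band_sd = s, floor_sd = fl)
}

# per-patient heterogeneity draws; seeded only by (cohort seed, patient)
# so they are identical across that patient's intervals
patient_profile <- function(spec, patient_idx) {
  set.seed(derive_seed(spec$seed, patient_idx, salt = 500))
  clamp <- function(x, b) pmin(pmax(x, -b), b)
  list(scale_jit = exp(clamp(stats::rnorm(1, 0, spec$patient_scale_sd), 0.5)),
       band_jit = exp(clamp(stats::rnorm(4, 0, spec$patient_band_sd), 1.5)),
       asym_jit = exp(clamp(stats::rnorm(1, 0, 0.5), 1.0)),
       depth_jit = clamp(stats::rnorm(1, 0, 0.35), 0.7),
       # EEG continuity: 1 = continuous background, lower = burst-attenuation
       # patterns (common after severe TBI); group-neutral, so it perturbs
       # entropy/regularity without carrying outcome information
       continuity = 0.45 + 0.52 * stats::plogis(stats::rnorm(1, 0.8, 1.2)))
}

# two-sided spectral amplitude profile for the shaped-noise synthesis;
# computed once per recording (bins outside 0.5-45 Hz carry no power)
noise_shape <- function(n, fs, band_sd, floor_sd) {
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  sigma2 <- numeric(n)
  bands <- band_scheme()[c("delta", "theta", "alpha", "beta")]
  for (b in names(bands)) {
    sel <- f >= bands[[b]][1] & f < bands[[b]][2]
    sigma2[sel] <- sigma2[sel] + 2 * n^2 * band_sd[[b]]^2 / sum(sel)
  }
  sel <- f >= 0.5 & f < 45
  w <- 1 / f[sel]
  sigma2[sel] <- sigma2[sel] + 2 * n^2 * floor_sd^2 * w / sum(w)
  nz <- which(sigma2 > 0)
  list(nz = nz, amp = sqrt(sigma2[nz] / 2))
}

# two independent shaped-noise channels per inverse FFT: Re and Im parts
# of the inverse transform of an (unconstrained) complex white spectrum
# are independent Gaussian processes with the same power spectrum
shaped_noise_pair <- function(n, shape) {
  z <- complex(length.out = n)
  z[shape$nz] <- complex(real = stats::rnorm(length(shape$nz)),
                         imaginary = stats::rnorm(length(shape$nz))) * shape$amp
  x <- stats::fft(z, inverse = TRUE) / n
  list(Re(x), Im(x))
}

#' Simulate one patient's EEG around an analysis interval
#'
#' Generates a 19-channel 256-Hz recording covering the stated hours
#' post-trauma for one synthetic patient: per channel, a sum of
#' band-limited Gaussian processes with outcome-conditioned amplitudes
#' plus a 1/f background; right-hemisphere channels scaled by the
#' asymmetry gain; a shared epochwise amplitude modulation at the group's
#' depth; flat-epoch and high-amplitude transient artifacts injected at
#' `artifact_rate` per 10-min window.  Deterministic given (spec seed,
#' patient index, start hour).
#'
#' @param spec a [cohort_spec()].
#' @param patient_idx integer patient index within the cohort.
#' @param outcome `"poor"` or `"good"`.
#' @param start_hour recording start, hours post-trauma.
#' @param duration_min recording length in minutes.
#' @param fs sample rate, Hz.
#' @return An [eeg_recording] with attribute `ground_truth` (band
#'   amplitudes, gains, modulation depth, artifact placements).
#' @export
simulate_eeg <- function(spec, patient_idx, outcome,
                         start_hour = 72, duration_min = 60, fs = 256) {
  pp <- patient_profile(spec, patient_idx)
  set.seed(derive_seed(spec$seed, patient_idx, round(start_hour)))
  n <- round(duration_min * 60 * fs)
  prof <- outcome_band_sd(spec, outcome, pp$scale_jit, pp$band_jit)
  nch <- length(CHANNELS_1020)
  shape <- noise_shape(n, fs, prof$band_sd, prof$floor_sd)
  x <- matrix(0, nch, n)
  for (i in seq(1, nch, by = 2)) {
    pair <- shaped_noise_pair(n, shape)
    x[i, ] <- pair[[1]]
    if (i + 1 <= nch) x[i + 1, ] <- pair[[2]]
  }
  g0 <- if (outcome == "poor") spec$asymmetry_poor else spec$asymmetry_good
  gain <- ifelse(CHANNELS_1020 %in% RIGHT_CHANNELS,
                 min(1, g0 * pp$asym_jit), 1)
  x <- x * gain

  depth0 <- if (outcome == "poor") spec$variability_poor else spec$variability_good
  depth <- min(0.8, max(0.02, depth0 + pp$depth_jit))

  # burst-attenuation envelope: 0.5-s blocks are "on" with probability
  # `continuity`, attenuated to 25% amplitude otherwise; normalised to
  # unit mean square so the patient's overall power is unchanged
  b <- pp$continuity
  g_lo <- 0.15
  g_hi <- sqrt((1 - (1 - b) * g_lo^2) / b)
  blk <- round(0.5 * fs)
  n_blk <- ceiling(n / blk)
  env_blk <- ifelse(stats::runif(n_blk) < b, g_hi, g_lo)
  env <- rep(env_blk, each = blk)[seq_len(n)]
  x <- sweep(x, 2, env, "*")
  ep_len <- round(10 * fs)
  n_ep <- floor(n / ep_len)
  mod_ep <- 1 + depth * stats::runif(n_ep, -1, 1)
  mod <- rep(mod_ep, each = ep_len)
  if (length(mod) < n) mod <- c(mod, rep(mod_ep[n_ep], n - length(mod)))
  x <- sweep(x, 2, mod, "*")

  artifacts <- list()
  n_win <- floor(duration_min / 10)
  for (w in seq_len(n_win)) {
    k <- stats::rpois(1, spec$artifact_rate)
    if (k < 1) next
    for (a in seq_len(k)) {
      e <- sample.int(60, 1) + (w - 1) * 60
      if (e > n_ep) next
      ch <- sample.int(nch, 1)
      idx <- ((e - 1) * ep_len + 1):(e * ep_len)
      if (stats::runif(1) < 0.5) {
        x[ch, idx] <- 0
        type <- "flat"
      } else {
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 200, 400)
        dur <- round(0.25 * fs)
        at <- sample.int(ep_len - dur, 1)
        pulse <- amp * (0.5 - 0.5 * cos(2 * pi * seq_len(dur) / dur))
        x[ch, idx[at:(at + dur - 1)]] <- x[ch, idx[at:(at + dur - 1)]] + pulse
        type <- "transient"
      }
      artifacts[[length(artifacts) + 1]] <-
        list(epoch = e, channel = CHANNELS_1020[ch], type = type)
    }
  }

  rec <- eeg_recording(sprintf("P%03d", patient_idx), x, fs,
                       trauma_offset = start_hour)
  attr(rec, "ground_truth") <- list(
    outcome = outcome, band_sd = prof$band_sd, floor_sd = prof$floor_sd,
    asymmetry_gain = min(1, g0 * pp$asym_jit),
    modulation_depth = depth, epoch_modulation = mod_ep,
    continuity = pp$continuity,
    artifacts = artifacts)
  rec
}

truncated_normal <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  x
}

#' Simulate the clinical covariate table and MAP series
#'
#' Outcome-conditioned admission covariates: older age, higher glucose,
#' lower MAP, worse motor/pupil/CT findings in the poor group (directions
#' only; magnitudes are generator calibration, not clinical claims).
#' GOSE is sampled uniformly within the outcome stratum (1-2 vs 3-8).
#' Every patient has hourly MAP entries covering hours 20-98.
#'
#' @param spec a [cohort_spec()].
#' @return List: `clinical` (validated clinical data.frame, plus an
#'   `outcome` column), `map` (long data.frame patient_id/hour/map_mmhg).
#' @export
simulate_clinical <- function(spec) {
  n <- spec$n_poor + spec$n_good
  outcomes <- rep(c("poor", "good"), c(spec$n_poor, spec$n_good))
  null_like <- !is.null(attr(spec, "neutralized"))
  rows <- list(); maps <- list()
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i, salt = 999))
    poor <- outcomes[i] == "poor"
    agep <- if (poor) spec$age_poor else spec$age_good
    # outcome-conditioned categorical priors (equalised for null cohorts)
    pr <- if (null_like) {
      list(motor = rep(1 / 6, 6), pupils = c(0.6, 0.25, 0.15),
           marshall = c(0.15, 0.25, 0.2, 0.15, 0.15, 0.1),
           edh = 0.12, tsah = 0.5, hypo = 0.25, hypox = 0.22,
           glu = c(8, 2), hb = c(13, 1.6))
    } else if (poor) {
      list(motor = c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03),
           pupils = c(0.35, 0.30, 0.35),
           marshall = c(0.05, 0.10, 0.20, 0.20, 0.25, 0.20),
           edh = 0.15, tsah = 0.65, hypo = 0.35, hypox = 0.30,
           glu = c(7.5 + spec$glucose_shift, 2.2), hb = c(12.4, 1.7))
    } else {
      list(motor = c(0.04, 0.08, 0.15, 0.20, 0.28, 0.25),
           pupils = c(0.80, 0.15, 0.05),
           marshall = c(0.25, 0.35, 0.20, 0.10, 0.06, 0.04),
           edh = 0.10, tsah = 0.40, hypo = 0.15, hypox = 0.15,
           glu = c(7.5, 1.8), hb = c(13.6, 1.5))
    }
    mapp <- if (poor) spec$map_poor else spec$map_good
    pid <- sprintf("P%03d", i)
    rows[[i]] <- data.frame(
      patient_id = pid,
      age = round(truncated_normal(1, agep[1], agep[2], 18), 1),
      motor_score = sample(1:6, 1, prob = pr$motor),
      pupils = sample(0:2, 1, prob = pr$pupils),
      marshall = sample(1:6, 1, prob = pr$marshall),
      edh = stats::rbinom(1, 1, pr$edh),
      tsah = stats::rbinom(1, 1, pr$tsah),
      hypotension = stats::rbinom(1, 1, pr$hypo),
      hypoxia = stats::rbinom(1, 1, pr$hypox),
      glucose = round(max(2.5, stats::rnorm(1, pr$glu[1], pr$glu[2])), 1),
      hemoglobin = round(min(20, max(5, stats::rnorm(1, pr$hb[1], pr$hb[2]))), 1),
      gose = if (poor) sample(1:2, 1) else sample(3:8, 1),
      outcome = outcomes[i],
      trauma_time = "2020-01-01T00:00:00",
      stringsAsFactors = FALSE)
    hours <- seq(20.5, 98.5, by = 1)
    pm <- stats::rnorm(1, mapp[1], 5)
    maps[[i]] <- data.frame(
      patient_id = pid, hour = hours,
      map_mmhg = round(pmin(180, pmax(40, pm + stats::rnorm(length(hours), 0, mapp[2] / 2))), 1),
      stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, rows)
  validate_clinical(clinical[, CLINICAL_COLUMNS])
  list(clinical = clinical, map = do.call(rbind, maps))
}

#' Simulate a cohort's per-window qEEG feature table in memory
#'
#' Runs the full extraction chain (simulate, filter, slice, screen, mask,
#' extract) for every patient and interval without touching disk.
#'
#' @param spec a [cohort_spec()].
#' @param intervals post-trauma hours to simulate and analyse.
#' @param config preprocessing thresholds.
#' @return List: `features` (per-window table), `clinical`, `map`.
#' @export
simulate_cohort_features <- function(spec, intervals = c(24, 48, 72, 96),
                                     config = preprocess_config()) {
  clin <- simulate_clinical(spec)
  outcomes <- clin$clinical$outcome
  feats <- list()
  for (i in seq_len(nrow(clin$clinical))) {
    for (iv in intervals) {
      rec <- simulate_eeg(spec, i, outcomes[i], start_hour = iv)
      feats[[length(feats) + 1]] <- recording_features(rec, iv, config)
    }
  }
  list(features = do.call(rbind, feats),
       clinical = clin$clinical, map = clin$map)
}

#' Write a synthetic cohort to disk
#'
#' Cohort directory layout: one EDF per (patient, interval) covering that
#' interval's hour, `clinical.csv`, `map.csv`, `ground_truth.json`
#' (per-recording generative parameters and artifact placements) and
#' `manifest.json` (the full spec and seed).
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created).
#' @param intervals hours to simulate.
#' @return `dir`, invisibly.
#' @export
simulate_cohort <- function(spec, dir, intervals = c(24, 48, 72, 96)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clin <- simulate_clinical(spec)
  utils::write.csv(clin$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(clin$map, file.path(dir, "map.csv"), row.names = FALSE)
  gt <- list()
  trauma <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  for (i in seq_len(nrow(clin$clinical))) {
    pid <- clin$clinical$patient_id[i]
    for (iv in intervals) {
      rec <- simulate_eeg(spec, i, clin$clinical$outcome[i], start_hour = iv)
      f <- file.path(dir, sprintf("%s_%02dh.edf", pid, iv))
      write_edf(rec, f, start_time = trauma + iv * 3600)
      g <- attr(rec, "ground_truth")
      g$band_sd <- as.list(g$band_sd)
      gt[[basename(f)]] <- g
    }
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- unclass(spec)
  manifest$trauma_time <- format(trauma, "%Y-%m-%dT%H:%M:%S")
  manifest$intervals <- intervals
  manifest$neutralized <- attr(spec, "neutralized")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
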