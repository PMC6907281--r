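# The 23 qEEG features: analytic cases, invariants, and equivalence with
# an independent brute-force periodogram oracle.

WIN2 <- 12 * EPOCH_LEN   # 2-min windows keep the unit tests quick

test_that("a pure alpha tone concentrates power where it should", {
  x <- matrix(tone(10, WIN2, amp = 1), 18, WIN2, byrow = TRUE)
  mw <- make_masked(x)
  spec <- welch_psd(mw)
  pw <- band_powers(spec)
  # unit-amplitude sine: band power = A^2/2
  expect_equal(pw$abs[["alpha"]], 0.5, tolerance = 0.01)
  expect_gt(pw$rel[["alpha"]], 0.99)
  expect_lt(pw$rel[["delta"]], 0.01)
  expect_equal(sef90(spec), 10, tolerance = 0.3)
})

test_that("relative powers always sum to one and bands partition the total", {
  for (seed in 1:5) {
    mw <- make_masked(noise_bp_matrix(WIN2, sd = 20, seed = seed))
    pw <- band_powers(welch_psd(mw))
    expect_equal(sum(pw$rel), 1, tolerance = 1e-6)
    expect_equal(sum(pw$abs), pw$total, tolerance = 1e-9)
    expect_true(all(pw$abs >= 0))
  }
})

test_that("an equal-power delta/alpha mixture splits evenly and has ADR 1", {
  x <- matrix(tone(2, WIN2, amp = 1) + tone(10, WIN2, amp = 1), 18, WIN2,
              byrow = TRUE)
  pw <- band_powers(welch_psd(make_masked(x)))
  expect_equal(pw$rel[["delta"]], 0.5, tolerance = 0.02)
  expect_equal(pw$rel[["alpha"]], 0.5, tolerance = 0.02)
  expect_equal(adr(pw), 1, tolerance = 0.05)
})

test_that("ADR orders delta-dominant below alpha-dominant activity", {
  set.seed(21)
  floor_x <- matrix(rnorm(18 * WIN2, sd = 0.5), 18, WIN2)
  alpha_x <- floor_x + matrix(tone(10, WIN2, amp = 20), 18, WIN2, byrow = TRUE)
  delta_x <- floor_x + matrix(tone(2, WIN2, amp = 20), 18, WIN2, byrow = TRUE)
  expect_gt(adr(band_powers(welch_psd(make_masked(alpha_x)))), 10)
  expect_lt(adr(band_powers(welch_psd(make_masked(delta_x)))), 0.1)
})

test_that("SEF90 matches the flat-spectrum closed form and is monotone", {
  set.seed(22)
  # band-limited white noise: SEF90 ~ 0.5 + 0.9 * 19.5 = 18.05
  bw <- signal::butter(6, c(0.5, 20) / 128, "pass")
  x <- t(apply(matrix(rnorm(18 * WIN2, sd = 20), 18), 1,
               function(r) as.numeric(signal::filtfilt(bw, r))))
  expect_equal(sef90(welch_psd(make_masked(x))), 18.05, tolerance = 0.5)

  lo <- matrix(tone(2, WIN2, amp = 10), 18, WIN2, byrow = TRUE)
  hi <- lo + matrix(tone(19, WIN2, amp = 10), 18, WIN2, byrow = TRUE)
  expect_gt(sef90(welch_psd(make_masked(hi))),
            sef90(welch_psd(make_masked(lo))))
})

test_that("variability reflects epoch-to-epoch band-power modulation", {
  # constant-amplitude tone: almost no epoch-to-epoch variation
  x <- matrix(tone(10, WIN2, amp = 30), 18, WIN2, byrow = TRUE)
  v <- variability(welch_psd(make_masked(x)))
  expect_lt(v[["alpha"]], 0.1)

  # amplitude alternating x3 every epoch: powers alternate P / 9P,
  # MAD/median = 4/5 = 0.8
  amp <- rep(rep(c(1, 3), 6), each = EPOCH_LEN) * 30
  x2 <- matrix(amp * tone(10, WIN2, amp = 1), 18, WIN2, byrow = TRUE)
  v2 <- variability(welch_psd(make_masked(x2)))
  expect_gt(v2[["alpha"]], 0.5)
  expect_equal(v2[["alpha"]], 0.8, tolerance = 0.05)

  # fewer than 8 valid epochs: undefined
  short <- make_masked(matrix(tone(10, 6 * EPOCH_LEN, amp = 30), 18,
                              6 * EPOCH_LEN, byrow = TRUE))
  expect_true(all(is.na(variability(welch_psd(short)))))
})

test_that("the brain symmetry index separates symmetric from one-sided EEG", {
  set.seed(23)
  # identical left and right chains: perfectly symmetric
  left <- noise_bp_matrix(WIN2, nd = 8, sd = 20, seed = 31)
  mid <- noise_bp_matrix(WIN2, nd = 2, sd = 20, seed = 32)
  sym <- rbind(left, left, mid)
  b <- bsi(welch_psd(make_masked(sym)))
  expect_lt(b[["bsi_total"]], 1e-6)
  expect_lt(b[["bsi_delta"]], 1e-6)

  # silent right hemisphere (tiny broadband floor): close to 1
  quiet <- noise_bp_matrix(WIN2, nd = 8, sd = 0.2, seed = 33)
  asym <- rbind(left, quiet, mid)
  b2 <- bsi(welch_psd(make_masked(asym)))
  expect_gt(b2[["bsi_total"]], 0.8)

  # independent same-distribution noise: small but nonzero
  right <- noise_bp_matrix(WIN2, nd = 8, sd = 20, seed = 34)
  b3 <- bsi(welch_psd(make_masked(rbind(left, right, mid))))
  expect_gt(b3[["bsi_total"]], 0)
  expect_lt(b3[["bsi_total"]], 0.5)
})

test_that("mirroring the montage leaves BSI unchanged", {
  set.seed(24)
  x <- noise_bp_matrix(WIN2, nd = 18, sd = 20, seed = 35)
  mirrored <- x[c(9:16, 1:8, 17:18), ]
  b1 <- bsi(welch_psd(make_masked(x)))
  b2 <- bsi(welch_psd(make_masked(mirrored)))
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("the centre of gravity tracks the power topography", {
  coords <- electrode_coordinates()
  # equal power everywhere: centred (the coordinate table is symmetric)
  ca <- matrix(tone(10, WIN2, amp = 20), 19, WIN2, byrow = TRUE)
  mw <- make_masked(noise_bp_matrix(WIN2, seed = 36), ca_data = ca)
  cg <- cog(mw)
  expect_equal(cg[["cog_x"]], 0, tolerance = 0.01)
  expect_equal(cg[["cog_y"]], 0, tolerance = 0.01)

  # all power on O1/O2: posterior, lateral-balanced
  ca2 <- matrix(0, 19, WIN2)
  ca2[match(c("O1", "O2"), CHANNELS_1020), ] <-
    matrix(tone(10, WIN2, amp = 20), 2, WIN2, byrow = TRUE)
  cg2 <- cog(make_masked(noise_bp_matrix(WIN2, seed = 37), ca_data = ca2))
  expect_lt(cg2[["cog_y"]], -0.5)
  expect_equal(cg2[["cog_x"]], 0, tolerance = 0.01)

  # point mass on F7: exactly F7's coordinates
  ca3 <- matrix(0, 19, WIN2)
  ca3[match("F7", CHANNELS_1020), ] <- tone(10, WIN2, amp = 20)
  cg3 <- cog(make_masked(noise_bp_matrix(WIN2, seed = 38), ca_data = ca3))
  f7 <- coords[coords$channel == "F7", ]
  expect_equal(cg3[["cog_x"]], f7$x, tolerance = 1e-9)
  expect_equal(cg3[["cog_y"]], f7$y, tolerance = 1e-9)
})

test_that("mean amplitude is the signal's standard deviation in microvolts", {
  x <- matrix(tone(10, WIN2, amp = 50), 18, WIN2, byrow = TRUE)
  expect_equal(mean_amplitude(make_masked(x)), 50 / sqrt(2), tolerance = 0.5)
  set.seed(25)
  g <- matrix(rnorm(18 * WIN2, sd = 20), 18, WIN2)
  expect_equal(mean_amplitude(make_masked(g)), 20, tolerance = 1)
  expect_equal(mean_amplitude(make_masked(2 * g)),
               2 * mean_amplitude(make_masked(g)), tolerance = 1e-9)
})

test_that("coherence spans its range from duplicated to independent signals", {
  set.seed(26)
  common <- tone(10, WIN2, amp = 20) + rnorm(WIN2, sd = 5)
  dup <- matrix(common, 18, WIN2, byrow = TRUE)
  expect_gte(coherence(make_masked(dup)), 1 - 1e-6)

  indep <- noise_bp_matrix(WIN2, sd = 20, seed = 41)
  expect_lt(coherence(make_masked(indep)), 0.2)

  # monotone in the shared-signal SNR
  msc_at <- function(snr) {
    shared <- tone(10, WIN2, amp = 20 * snr)
    x <- sweep(noise_bp_matrix(WIN2, sd = 20, seed = 42), 2, shared, "+")
    coherence(make_masked(x))
  }
  vals <- vapply(c(0.25, 1, 4), msc_at, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("Shannon entropy matches degenerate, uniform and oracle cases", {
  # constant signal: one occupied bin
  expect_equal(shannon_entropy(make_masked(matrix(42, 18, WIN2))), 0)

  # equal mass in all 100 bins: log2(100)
  centers <- seq(-148.5, 148.5, by = 3)
  u <- matrix(rep(centers, length.out = WIN2), 18, WIN2, byrow = TRUE)
  expect_equal(shannon_entropy(make_masked(u)), log2(100), tolerance = 1e-6)

  # Gaussian: strictly between, and equal to a direct histogram oracle
  set.seed(27)
  g <- matrix(rnorm(WIN2, sd = 30), 1, WIN2)
  h <- shannon_entropy(make_masked(g))
  expect_gt(h, 0); expect_lt(h, log2(100))
  cnt <- table(cut(pmin(pmax(g[1, ], -150), 150 - 1e-9),
                   breaks = seq(-150, 150, length.out = 101)))
  p <- cnt[cnt > 0] / sum(cnt)
  expect_equal(h, -sum(p * log2(p)), tolerance = 1e-9)
})

test_that("regularity is high for continuous and low for burst-like EEG", {
  x <- matrix(tone(10, WIN2, amp = 30), 18, WIN2, byrow = TRUE)
  expect_gt(regularity(make_masked(x)), 0.95)

  # burst-suppression-like: activity on 10% of each epoch
  set.seed(28)
  burst <- matrix(rnorm(18 * WIN2, sd = 1), 18, WIN2)
  on <- rep(rep(c(1, 0), c(EPOCH_LEN / 10, EPOCH_LEN - EPOCH_LEN / 10)), 12)
  burst <- sweep(burst, 2, on * 50, `*`) + burst * 0.02
  expect_lt(regularity(make_masked(burst)), 0.5)

  # scale invariance
  y <- noise_bp_matrix(WIN2, sd = 15, seed = 43)
  expect_equal(regularity(make_masked(y)), regularity(make_masked(7 * y)),
               tolerance = 1e-12)
})

test_that("extract_features returns the 23 named features, deterministically", {
  set.seed(29)
  ca <- matrix(rnorm(19 * WIN2, sd = 18), 19, WIN2)
  bp <- noise_bp_matrix(WIN2, sd = 20, seed = 44)
  mw <- make_masked(bp, ca_data = ca)
  fv <- extract_features(mw)
  expect_identical(names(fv), QEEG_FEATURE_NAMES)
  expect_length(fv, 23)
  expect_identical(fv, extract_features(mw))
  # bounded features honour their ranges
  expect_true(all(fv[c("bsi_total", "bsi_delta", "coherence",
                       "var_delta", "var_theta", "var_alpha", "var_beta",
                       "regularity")] >= 0))
  expect_true(all(fv[c("bsi_total", "bsi_delta", "coherence", "regularity")] <= 1))
  expect_true(all(abs(fv[c("cog_x", "cog_y")]) <= 1))
})

test_that("spectral features agree with the brute-force periodogram oracle", {
  bands <- band_scheme()
  # tone frequencies stay ~1 Hz clear of the band edges: near an edge the
  # two estimators split leakage across neighbouring bands differently
  # (0.25 Hz Hamming mainlobe vs 0.1 Hz rectangular), which measures
  # resolution, not correctness
  # ... and at least 0.5 Hz apart: closer tones beat at the epoch scale,
  # making the signal non-stationary within an epoch, where tapered and
  # untapered estimators legitimately differ
  interior <- function(k) {
    lo <- c(1.5, 5, 9, 14); hi <- c(3, 7, 12, 19)
    repeat {
      b <- sample(4, k, replace = TRUE)
      f <- runif(k, lo[b], hi[b])
      if (k < 2 || min(dist(f)) >= 0.5) return(f)
    }
  }
  for (seed in 1:20) {
    set.seed(100 + seed)
    freqs <- interior(3)
    amps <- runif(3, 5, 30)
    x <- matrix(rnorm(18 * WIN2, sd = runif(1, 5, 15)), 18, WIN2)
    for (k in 1:3)
      x <- x + matrix(tone(freqs[k], WIN2, amps[k], phase = runif(1, 0, 2 * pi)),
                      18, WIN2, byrow = TRUE)
    spec <- welch_psd(make_masked(x))
    pw <- band_powers(spec)
    op <- oracle_psd(x)
    for (b in c("delta", "theta", "alpha", "beta")) {
      expect_equal(pw$abs[[b]], oracle_band_power(op, bands[[b]]),
                   tolerance = 0.05 * max(pw$abs[[b]], 1e-3))
      expect_equal(pw$rel[[b]],
                   oracle_band_power(op, bands[[b]]) /
                     oracle_band_power(op, bands$total),
                   tolerance = 0.05)
    }
    expect_equal(sef90(spec), oracle_sef90(op), tolerance = 0.5)
  }
})

test_that("total power obeys Parseval against the time-domain variance", {
  set.seed(30)
  bw <- signal::butter(6, c(0.5, 20) / 128, "pass")
  x <- t(apply(matrix(rnorm(18 * WIN2, sd = 20), 18), 1,
               function(r) as.numeric(signal::filtfilt(bw, r))))
  pw <- band_powers(welch_psd(make_masked(x)))
  expect_equal(pw$total, mean(apply(x, 1, var)), tolerance = 0.1 * pw$total)
})

test_that("missing features propagate without breaking the vector", {
  # pure delta tone: alpha power ~ 0 but defined; flat-right BSI defined;
  # kill the delta path instead: zero delta -> ADR missing
  x <- matrix(tone(16, WIN2, amp = 20), 18, WIN2, byrow = TRUE)
  fv <- extract_features(make_masked(x))
  expect_identical(names(fv), QEEG_FEATURE_NAMES)
  # delta power of a pure 16 Hz tone is ~ 0 but positive (leakage); the
  # ratio must still be finite or NA, never infinite
  expect_false(is.infinite(fv[["adr"]]))
})
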