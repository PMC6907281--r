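# The outcome-conditioned synthetic cohort generator.

test_that("simulation is deterministic: identical spec and seed, identical bytes", {
  spec <- cohort_spec(n_poor = 1, n_good = 1, seed = 21)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_cohort(spec, d1, intervals = 24)
  simulate_cohort(spec, d2, intervals = 24)
  for (f in list.files(d1)) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]],
                     label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a zero artifact rate yields a window the detector leaves untouched", {
  spec <- cohort_spec(n_poor = 1, n_good = 1, seed = 22, artifact_rate = 0)
  rec <- simulate_eeg(spec, 1, "good", start_hour = 24, duration_min = 10)
  rec <- qeegpredict:::filter_recording(rec)
  ca <- to_montage(rec, "common-average")
  mask <- detect_artifacts(make_window(ca$data, "common-average",
                                       labels = CHANNELS_1020))
  expect_equal(sum(!mask$valid), 0)
})

test_that("injected artifacts are found where the ground truth says they are", {
  spec <- cohort_spec(n_poor = 1, n_good = 1, seed = 23, artifact_rate = 2)
  rec <- simulate_eeg(spec, 1, "good", start_hour = 24, duration_min = 10)
  gt <- attr(rec, "ground_truth")
  expect_gt(length(gt$artifacts), 0)
  rec <- qeegpredict:::filter_recording(rec)
  ca <- to_montage(rec, "common-average")
  mask <- detect_artifacts(make_window(ca$data, "common-average",
                                       labels = CHANNELS_1020))
  # every transient lands on its planted (epoch, channel); flat epochs in
  # the common average become the negated channel mean and may pass
  transients <- Filter(function(a) a$type == "transient", gt$artifacts)
  for (a in transients)
    expect_false(mask$valid[a$epoch, a$channel])
})

test_that("outcome groups differ in the directions the features measure", {
  spec <- cohort_spec(n_poor = 2, n_good = 2, seed = 24, artifact_rate = 0)
  one_window_features <- function(idx, outcome) {
    rec <- simulate_eeg(spec, idx, outcome, start_hour = 72, duration_min = 10)
    rec <- qeegpredict:::filter_recording(rec)
    ca <- to_montage(rec, "common-average")
    bp <- to_montage(rec, "longitudinal-bipolar")
    caw <- make_window(ca$data, "common-average", labels = CHANNELS_1020)
    mask <- detect_artifacts(caw)
    extract_features(apply_mask(make_window(bp$data), mask, caw))
  }
  # paired by patient index: identical heterogeneity draws, so the
  # outcome effects are isolated from between-patient variation
  fg <- (one_window_features(1, "good") + one_window_features(2, "good")) / 2
  fp <- (one_window_features(1, "poor") + one_window_features(2, "poor")) / 2
  expect_gt(fg[["rel_alpha"]], fp[["rel_alpha"]])       # alpha suppression
  expect_gt(fg[["mean_amplitude"]], 1.5 * fp[["mean_amplitude"]])  # amplitude ratio
  expect_gt(fp[["bsi_total"]], fg[["bsi_total"]])       # asymmetry
  expect_gt(fg[["var_alpha"]], fp[["var_alpha"]])       # modulation depth
})

test_that("asymmetry raises the symmetry index against a matched control", {
  base <- cohort_spec(n_poor = 1, n_good = 1, seed = 25, artifact_rate = 0)
  ctrl <- cohort_spec(n_poor = 1, n_good = 1, seed = 25, artifact_rate = 0,
                      asymmetry_poor = 1)
  bsi_of <- function(spec) {
    rec <- simulate_eeg(spec, 1, "poor", start_hour = 72, duration_min = 10)
    rec <- qeegpredict:::filter_recording(rec)
    bp <- to_montage(rec, "longitudinal-bipolar")
    ca <- to_montage(rec, "common-average")
    caw <- make_window(ca$data, "common-average", labels = CHANNELS_1020)
    fv <- extract_features(apply_mask(make_window(bp$data),
                                      detect_artifacts(caw), caw))
    fv[["bsi_total"]]
  }
  expect_gt(bsi_of(base), bsi_of(ctrl))
})

test_that("group separation weakens as the amplitude ratio approaches one", {
  sep_at <- function(ratio) {
    spec <- cohort_spec(n_poor = 1, n_good = 1, seed = 26, artifact_rate = 0,
                        amplitude_ratio = ratio, alpha_suppression = 1)
    amp_of <- function(outcome, idx) {
      rec <- simulate_eeg(spec, idx, outcome, start_hour = 72, duration_min = 10)
      rec <- qeegpredict:::filter_recording(rec)
      bp <- to_montage(rec, "longitudinal-bipolar")
      mean_amplitude(apply_mask(make_window(bp$data),
                                detect_artifacts(make_window(
                                  to_montage(rec, "common-average")$data,
                                  "common-average", labels = CHANNELS_1020))))
    }
    abs(amp_of("good", 1) - amp_of("poor", 2))
  }
  seps <- vapply(c(0.5, 0.8, 1.0), sep_at, numeric(1))
  expect_true(all(diff(seps) < 0))
})

test_that("clinical covariates follow the outcome-conditioned distributions", {
  spec <- cohort_spec(n_poor = 200, n_good = 200, seed = 27)
  cl <- simulate_clinical(spec)$clinical
  poor <- cl$outcome == "poor"
  age_diff <- mean(cl$age[poor]) - mean(cl$age[!poor])
  expect_gt(age_diff, 16); expect_lt(age_diff, 24)      # ~20 y by construction
  expect_gt(mean(cl$glucose[poor]) - mean(cl$glucose[!poor]), 1)
  expect_true(all(cl$gose[poor] <= 2))
  expect_true(all(cl$gose[!poor] >= 3))

  # null cohort: identical distributions across labels
  nspec <- null_cohort_spec(n_poor = 200, n_good = 200, seed = 28)
  ncl <- simulate_clinical(nspec)$clinical
  npoor <- ncl$outcome == "poor"
  expect_gt(suppressWarnings(
    ks.test(ncl$glucose[npoor], ncl$glucose[!npoor])$p.value), 0.01)
  expect_gt(suppressWarnings(
    ks.test(ncl$age[npoor], ncl$age[!npoor])$p.value), 0.01)
  expect_true(all(c("amplitude_ratio", "age", "glucose_shift") %in%
                    attr(nspec, "neutralized")))
})

test_that("every patient's MAP series covers the four analysis intervals", {
  spec <- cohort_spec(n_poor = 3, n_good = 3, seed = 29)
  mp <- simulate_clinical(spec)$map
  for (pid in unique(mp$patient_id)) for (iv in c(24, 48, 72, 96)) {
    md <- mp[mp$patient_id == pid, ]
    expect_false(is.na(map_at_interval(md, iv, 0)))
  }
})

test_that("the cohort directory carries ground truth and a full manifest", {
  spec <- cohort_spec(n_poor = 1, n_good = 1, seed = 30)
  d <- file.path(tempdir(), "gtdir")
  simulate_cohort(spec, d, intervals = 48)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_length(gt, 2)
  expect_true(all(c("outcome", "band_sd", "asymmetry_gain", "modulation_depth")
                  %in% names(gt[[1]])))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 30)
  expect_equal(man$amplitude_ratio, 0.5)
  expect_true(file.exists(file.path(d, "clinical.csv")))
  expect_true(file.exists(file.path(d, "map.csv")))
  unlink(d, recursive = TRUE)
})
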