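# Clinical covariates, outcome labels and model-ready observation tables.

IMPACT_COLUMNS <- c("motor_score", "pupils", "marshall", "edh", "tsah",
                    "hypotension", "hypoxia", "glucose", "hemoglobin")

CLINICAL_COLUMNS <- c("patient_id", "age", IMPACT_COLUMNS, "gose")

PUPIL_LEVELS <- c("both" = 0L, "one" = 1L, "none" = 2L)

#' Load and validate the clinical covariate table
#'
#' One row per patient: age, the ten IMPACT admission parameters (age,
#' GCS motor score, pupillary reactivity, Marshall CT class, epidural
#' hematoma, traumatic subarachnoid hemorrhage, hypotension, hypoxia,
#' glucose, hemoglobin) and the 12-month GOSE.  Categoricals are coded as
#' ordinal integers (pupils both/one/none -> 0/1/2, Marshall I-VI -> 1-6,
#' binaries 0/1); glucose in mmol/L, hemoglobin in g/dL.  Validation is
#' strict with row-numbered messages.
#'
#' @param path CSV file.
#' @return data.frame of validated `ClinicalRecord` rows.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("clinical table is missing column(s): ", paste(missing_cols, collapse = ", "))
  validate_clinical(df)
}

validate_clinical <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("clinical table: duplicated patient_id ",
         df$patient_id[duplicated(df$patient_id)][1])
  if (is.character(df$pupils))
    df$pupils <- PUPIL_LEVELS[df$pupils]
  checks <- list(
    age = function(x) x >= 18,
    motor_score = function(x) x %in% 1:6,
    pupils = function(x) x %in% 0:2,
    marshall = function(x) x %in% 1:6,
    edh = function(x) x %in% 0:1,
    tsah = function(x) x %in% 0:1,
    hypotension = function(x) x %in% 0:1,
    hypoxia = function(x) x %in% 0:1,
    glucose = function(x) x > 0 & x < 60,
    hemoglobin = function(x) x > 2 & x < 25,
    gose = function(x) x %in% 1:8
  )
  for (col in names(checks)) {
    bad <- which(is.na(df[[col]]) | !checks[[col]](df[[col]]))
    if (length(bad))
      stop(sprintf("clinical table: invalid %s at row %d (value %s)",
                   col, bad[1], as.character(df[[col]][bad[1]])))
  }
  df
}

#' Load the long-format MAP series
#'
#' Columns `patient_id`, `hour` (post-trauma), `map_mmhg`.  Values outside
#' the physiologic range 20-200 mmHg are rejected with the offending row
#' number.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "hour", "map_mmhg")
  if (!all(need %in% names(df)))
    stop("MAP table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(df$map_mmhg) | df$map_mmhg < 20 | df$map_mmhg > 200)
  if (length(bad))
    stop(sprintf("MAP table: implausible value %s at row %d",
                 as.character(df$map_mmhg[bad[1]]), bad[1]))
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Dichotomize the extended Glasgow Outcome Scale
#'
#' Primary scheme `"1-2"`: poor = GOSE 1-2 (death/vegetative) vs good =
#' 3-8.  Secondary scheme `"1-4"`: poor = GOSE 1-4 (death to severe
#' disability) vs good = 5-8.
#'
#' @param gose integer 1..8 (vectorised).
#' @param scheme `"1-2"` or `"1-4"`.
#' @return Factor with levels `good`, `poor`.
#' @export
dichotomize_gose <- function(gose, scheme = c("1-2", "1-4")) {
  scheme <- match.arg(scheme)
  if (any(is.na(gose)) || any(!(gose %in% 1:8)))
    stop("gose must be in 1..8")
  cut <- if (scheme == "1-2") 2 else 4
  factor(ifelse(gose <= cut, "poor", "good"), levels = c("good", "poor"))
}

#' MAP summarised at an analysis interval
#'
#' Mean of the MAP entries belonging to the same 60-min segment used for
#' the EEG (the nominal hour plus its fallback shift).  Charted MAP values
#' are typically hourly spot checks whose timestamps need not align with
#' the hour grid, so an entry belongs to the segment when it lies within
#' half an hour of it.  When the segment holds no entry, the nearest entry
#' within 2 h is used; otherwise NA.
#'
#' @param map_df long MAP table for one patient (columns hour, map_mmhg).
#' @param interval nominal hour post-trauma.
#' @param fallback_shift shift (hours) actually used for the EEG segment.
#' @return mmHg, or NA.
#' @export
map_at_interval <- function(map_df, interval, fallback_shift = 0) {
  if (!nrow(map_df)) return(NA_real_)
  lo <- interval + fallback_shift
  hi <- lo + 1
  inside <- map_df$hour >= lo - 0.5 & map_df$hour < hi + 0.5
  if (any(inside)) return(mean(map_df$map_mmhg[inside]))
  d <- pmax(0, lo - map_df$hour, map_df$hour - hi)
  if (min(d) <= 2) return(map_df$map_mmhg[which.min(d)])
  NA_real_
}

#' Assemble the model-ready observation table
#'
#' One interval: one row per usable window (at most six per patient),
#' columns = the 23 qEEG features, MAP at the interval, and age.  Two
#' intervals: window k of the first interval is paired with window k of
#' the second (feature columns suffixed `_<interval>h`), keeping at most
#' six rows per patient.  With `include_impact`, the nine non-age IMPACT
#' admission parameters are appended.  Rows with any missing modelled
#' value are dropped (the Random-Forest stage excludes observations with
#' missing data); the dropped count is recorded in attribute `n_dropped`.
#'
#' @param features per-window feature table from [recording_features()]
#'   (or the cohort-level equivalent).
#' @param clin validated clinical table.
#' @param map_df long MAP table.
#' @param intervals one or two of 24/48/72/96.
#' @param include_impact append the 9 IMPACT columns?
#' @param scheme GOSE dichotomy passed to [dichotomize_gose()].
#' @return data.frame with `patient_id`, `label`, and the modelled columns;
#'   attributes `n_dropped`, `excluded_patients`, `feature_cols`.
#' @export
assemble <- function(features, clin, map_df, intervals,
                     include_impact = FALSE, scheme = "1-2") {
  stopifnot(length(intervals) %in% 1:2, all(intervals %in% c(24, 48, 72, 96)))
  intervals <- sort(intervals)
  unknown <- setdiff(unique(features$patient_id), clin$patient_id)
  if (length(unknown))
    warning("patients in features but not in the clinical table, excluded: ",
            paste(unknown, collapse = ", "))
  features <- features[features$patient_id %in% clin$patient_id, , drop = FALSE]
  clin <- clin[clin$patient_id %in% unique(features$patient_id), , drop = FALSE]
  feat_cols <- QEEG_FEATURE_NAMES

  one_interval <- function(iv, suffix) {
    fi <- features[features$interval == iv, , drop = FALSE]
    if (!nrow(fi)) return(NULL)
    map_vals <- vapply(seq_len(nrow(fi)), function(r) {
      md <- map_df[map_df$patient_id == fi$patient_id[r], , drop = FALSE]
      map_at_interval(md, iv, fi$fallback_shift[r])
    }, numeric(1))
    out <- fi[, c("patient_id", "window_index", feat_cols)]
    out[[paste0("map", suffix)]] <- map_vals
    names(out)[match(feat_cols, names(out))] <- paste0(feat_cols, suffix)
    out
  }

  if (length(intervals) == 1) {
    tab <- one_interval(intervals, "")
  } else {
    sfx <- paste0("_", intervals, "h")
    a <- one_interval(intervals[1], sfx[1])
    b <- one_interval(intervals[2], sfx[2])
    tab <- if (is.null(a) || is.null(b)) NULL else
      merge(a, b, by = c("patient_id", "window_index"))
  }
  if (is.null(tab) || !nrow(tab))
    stop("no observations available for interval(s) ",
         paste(intervals, collapse = "+"))

  idx <- match(tab$patient_id, clin$patient_id)
  tab$age <- clin$age[idx]
  if (include_impact)
    for (col in IMPACT_COLUMNS) tab[[col]] <- clin[[col]][idx]
  tab$label <- dichotomize_gose(clin$gose[idx], scheme)

  model_cols <- setdiff(names(tab), c("patient_id", "window_index", "label"))
  complete <- stats::complete.cases(tab[, model_cols, drop = FALSE])
  n_dropped <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]
  tab <- tab[order(tab$patient_id, tab$window_index), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, n_dropped = n_dropped, excluded_patients = unknown,
            feature_cols = model_cols)
}
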