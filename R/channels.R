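#' Canonical 10-20 channel set and derived montages
#'
#' The 19 scalp electrodes of the International 10-20 System in the fixed
#' order used throughout the package, the 18 longitudinal-bipolar ("double
#' banana") derivations, the 8 homologous left/right derivation pairs used
#' by the brain symmetry index, and the unit-disc electrode coordinates used
#' by the centre-of-gravity feature.
#'
#' @name montage_constants
NULL

#' @rdname montage_constants
#' @export
CHANNELS_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

#' @rdname montage_constants
#' @export
BIPOLAR_PAIRS <- matrix(c(
  "Fp1", "F7",
  "F7",  "T3",
  "T3",  "T5",
  "T5",  "O1",
  "Fp1", "F3",
  "F3",  "C3",
  "C3",  "P3",
  "P3",  "O1",
  "Fp2", "F8",
  "F8",  "T4",
  "T4",  "T6",
  "T6",  "O2",
  "Fp2", "F4",
  "F4",  "C4",
  "C4",  "P4",
  "P4",  "O2",
  "Fz",  "Cz",
  "Cz",  "Pz"
), ncol = 2, byrow = TRUE)

#' @rdname montage_constants
#' @export
BIPOLAR_LABELS <- paste(BIPOLAR_PAIRS[, 1], BIPOLAR_PAIRS[, 2], sep = "-")

# Indices (into BIPOLAR_LABELS) of homologous left/right derivation pairs.
# Left temporal + parasagittal chains against their right mirror images;
# midline Fz-Cz and Cz-Pz have no mirror and are excluded.
#' @rdname montage_constants
#' @export
BSI_PAIRS <- cbind(left = 1:8, right = 9:16)

# Right-hemisphere electrodes (used by the synthetic asymmetry effect).
RIGHT_CHANNELS <- c("Fp2", "F4", "F8", "C4", "T4", "P4", "T6", "O2")

#' Unit-disc 10-20 electrode coordinates
#'
#' Planar projection of the 10-20 positions onto the unit disc: x runs from
#' -1 (left) to +1 (right), y from -1 (posterior) to +1 (anterior), Cz at
#' the origin.  The table is left/right and anterior/posterior symmetric so
#' spatially uniform power has its centre of gravity at (0, 0).
#'
#' @return A data.frame with columns `channel`, `x`, `y` (19 rows).
#' @export
electrode_coordinates <- function() {
  data.frame(
    channel = CHANNELS_1020,
    x = c(-0.31, 0.31, -0.81, -0.45, 0, 0.45, 0.81,
          -1, -0.5, 0, 0.5, 1,
          -0.81, -0.45, 0, 0.45, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.45, 0.5, 0.45, 0.59,
          0, 0, 0, 0, 0,
          -0.59, -0.45, -0.5, -0.45, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Frequency band scheme
#'
#' The classical clinical bands delta (0.5-4 Hz), theta (4-8 Hz), alpha
#' (8-13 Hz) and beta (13-20 Hz).  Total power is defined over 0.5-20 Hz.
#' Band edges are shared between neighbouring bands; band integrals use the
#' trapezoidal rule on each closed interval so the four bands partition the
#' total range exactly (each interior edge contributes half a trapezoid to
#' each side).
#'
#' @return Named list of `c(lo, hi)` pairs plus a `total` range, in Hz.
#' @export
band_scheme <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 13),
    beta  = c(13, 20),
    total = c(0.5, 20)
  )
}

# Canonicalize an EDF channel label: strip "EEG " prefixes, reference
# suffixes ("-REF", "-LE", "-A1A2"), whitespace; case-insensitive; maps the
# modern temporal names (T7/T8/P7/P8) onto the classical T3/T4/T5/T6.
canonical_channel <- function(label) {
  lab <- toupper(trimws(label))
  lab <- sub("^EEG[ _]*", "", lab)
  lab <- sub("[-_ ](REF|LE|AVG|A1A2|A1|A2)$", "", lab)
  lab <- trimws(lab)
  synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  if (lab %in% names(synonyms)) lab <- synonyms[[lab]]
  canon <- CHANNELS_1020[match(lab, toupper(CHANNELS_1020))]
  if (is.na(canon)) NA_character_ else canon
}
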