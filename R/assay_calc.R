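# Oxidative-stress assay calculators.
#
# The wet-lab arm of the study quantified reduced glutathione (GSH),
# superoxide dismutase (SOD), catalase (CAT) and total protein in brain
# homogenate via spectrophotometric standard curves. These functions
# implement the printed formulas and regression inversions exactly; all are
# affine in their leading input, so intercept readings return 0 and
# inversions round-trip to machine precision.
#
# Readings below a standard curve's intercept yield negative amounts; they
# are returned as-is with a warning rather than clipped, leaving the call to
# the analyst.

warn_negative <- function(x, what) {
  if (any(x < 0)) {
    warning(what, " below the standard-curve intercept gives a negative ",
            "amount; returned unclipped")
  }
  x
}

#' GSH content from DTNB absorbance
#'
#' Reduced-glutathione content from absorbance at 412 nm:
#' `((Y - 0.00314) / 0.034) * DF / BT * VU`. The printed formula carries no
#' parentheses; 0.00314 and 0.034 are read as the calibration intercept and
#' slope, so the absorbance is converted first and the volume factors scale
#' the result (micrograms per mg tissue scale).
#'
#' @param Y Absorbance at 412 nm (unitless, finite, >= 0).
#' @param DF Dilution factor (> 0); 1 in the source protocol.
#' @param BT Brain-tissue homogenate volume in mL (> 0).
#' @param VU Aliquot volume in mL (> 0).
#' @return GSH content; vectorized over readings.
#' @export
gsh_content <- function(Y, DF = 1, BT = 1, VU = 1) {
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y)) || any(Y < 0)) {
    stop_input("'Y' must be finite nonnegative absorbance")
  }
  for (nm in c("DF", "BT", "VU")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_input("'", nm, "' must be strictly positive")
    }
  }
  warn_negative(((Y - 0.00314) / 0.034) * DF / BT * VU, "GSH absorbance")
}

#' SOD amount from the standard curve
#'
#' Inverts the printed SOD regression `Y = 0.0095 x + 0.1939` (absorbance at
#' 325 nm): returns `(Y - 0.1939) / 0.0095`. The source states the standard
#' curve volumes without units for x, so the result is in standard-curve
#' units.
#'
#' @param Y Absorbance at 325 nm (finite).
#' @return Amount `x` on the standard-curve scale; vectorized.
#' @export
sod_amount <- function(Y) {
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y))) {
    stop_input("'Y' must be finite absorbance")
  }
  warn_negative((Y - 0.1939) / 0.0095, "SOD absorbance")
}

#' Catalase activity
#'
#' Catalase activity from the decline of hydrogen peroxide absorbance at
#' 240 nm: `delta_od / (E * sample_volume * protein_mg)` with the hydrogen
#' peroxide extinction coefficient `E = 0.071` mmol^-1 cm^-1. The printed
#' formula chains the divisions without parentheses; extinction coefficient,
#' sample volume and protein are all read as denominators, the standard
#' normalization of catalase activity per mL and per mg protein.
#'
#' @param delta_od Absorbance change per minute (>= 0 in normal operation).
#' @param sample_volume Sample volume in mL (> 0).
#' @param protein_mg Protein amount in mg (> 0).
#' @return Activity; vectorized.
#' @export
cat_activity <- function(delta_od, sample_volume, protein_mg) {
  if (!is.numeric(delta_od) || anyNA(delta_od) || any(!is.finite(delta_od))) {
    stop_input("'delta_od' must be finite")
  }
  for (nm in c("sample_volume", "protein_mg")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_input("'", nm, "' must be strictly positive")
    }
  }
  delta_od / (0.071 * sample_volume * protein_mg)
}

#' Protein content from the BSA standard curve
#'
#' Inverts the printed Bradford-style BSA regression
#' `Y = 0.00007571 x + 0.0000476`: returns `(Y - 0.0000476) / 0.00007571`,
#' in standard-curve units.
#'
#' @param Y Absorbance (finite).
#' @return Protein amount `x` on the standard-curve scale; vectorized.
#' @export
protein_content <- function(Y) {
  if (!is.numeric(Y) || anyNA(Y) || any(!is.finite(Y))) {
    stop_input("'Y' must be finite absorbance")
  }
  warn_negative((Y - 0.0000476) / 0.00007571, "protein absorbance")
}

#' Compute all assay columns for a reading table
#'
#' Applies the four calculators to a delimited table of readings. Columns
#' are matched by name and each output column is added only when its inputs
#' are present: `gsh` from (`gsh_y`, `df`, `bt`, `vu`), `sod` from `sod_y`,
#' `cat` from (`delta_od`, `sample_volume`, `protein_mg`), `protein` from
#' `protein_y`.
#'
#' @param readings Data frame of assay readings.
#' @return The input with computed columns appended.
#' @export
compute_assay_table <- function(readings) {
  if (!is.data.frame(readings)) stop_input("'readings' must be a data frame")
  if (all(c("gsh_y", "df", "bt", "vu") %in% names(readings))) {
    readings$gsh <- gsh_content(readings$gsh_y, readings$df, readings$bt,
                                readings$vu)
  }
  if ("sod_y" %in% names(readings)) {
    readings$sod <- sod_amount(readings$sod_y)
  }
  if (all(c("delta_od", "sample_volume", "protein_mg") %in%
          names(readings))) {
    readings$cat <- cat_activity(readings$delta_od, readings$sample_volume,
                                 readings$protein_mg)
  }
  if ("protein_y" %in% names(readings)) {
    readings$protein <- protein_content(readings$protein_y)
  }
  readings
}
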