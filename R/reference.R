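.measurementColumn <- function(measurement) {
  measurement <- match.arg(measurement, .MEASUREMENTS)
  .MEASUREMENT_COLS[[measurement]]
}

#' Compute young-reference norms for one sex and measurement
#'
#' Selects the animals of the given sex whose age falls inside the closed
#' reference window and whose measurement is non-missing, and returns the
#' arithmetic mean, sample SD (n-1 denominator), and n.
#'
#' @param cohort A phenotype `data.frame` as returned by [readCohort()] or
#'   [generateCohort()].
#' @param sex `"male"` or `"female"`.
#' @param measurement `"grip"`, `"mass"` or `"treadmill"`.
#' @param ageWindow Closed age interval in months, default `c(4, 9)` — the
#'   usual young reference for males (`c(6, 7)` mirrors the female cohorts).
#' @return A one-row `data.frame` with columns `sex`, `measurement`,
#'   `window_lo`, `window_hi`, `n`, `mean`, `sd`.
#' @examples
#' cohort <- generateCohort(defaultCohortConfig("male"))
#' computeReference(cohort, "male", "grip")
#' @export
computeReference <- function(cohort, sex, measurement, ageWindow = c(4, 9)) {
  measurement <- match.arg(measurement, .MEASUREMENTS)
  col <- .measurementColumn(measurement)
  keep <- cohort$sex == sex &
    cohort$age_months >= ageWindow[1] & cohort$age_months <= ageWindow[2] &
    !is.na(cohort[[col]])
  vals <- cohort[[col]][keep]
  if (length(vals) < 2L)
    stop(sprintf(
      "insufficient reference animals: %d %s with non-missing %s in [%g, %g] months (need >= 2)",
      length(vals), sex, measurement, ageWindow[1], ageWindow[2]))
  data.frame(sex = sex, measurement = measurement,
             window_lo = ageWindow[1], window_hi = ageWindow[2],
             n = length(vals), mean = mean(vals), sd = sd(vals))
}

#' Derive a deficit cutoff from reference norms
#'
#' The cutoff is the reference mean minus two standard deviations,
#' optionally rounded to the nearest integer unit as in published tables.
#'
#' @param norms A one-row norms `data.frame` from [computeReference()].
#' @param rounding `"none"` (default; classification uses the unrounded
#'   value) or `"integer"`.
#' @return The cutoff, in the measurement's units.
#' @export
deriveCutoff <- function(norms, rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  cut <- norms$mean - 2 * norms$sd
  if (rounding == "integer") cut <- round(cut)
  cut
}

#' Derive the full sex-specific cutoff set from a cohort
#'
#' Convenience wrapper running [computeReference()] and [deriveCutoff()] for
#' all three criteria.
#'
#' @inheritParams computeReference
#' @inheritParams deriveCutoff
#' @return A [CutoffSet-class].
#' @export
deriveCutoffs <- function(cohort, sex, ageWindow = c(4, 9),
                          rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  norms <- do.call(rbind, lapply(.MEASUREMENTS, function(m)
    computeReference(cohort, sex, m, ageWindow)))
  cuts <- setNames(vapply(seq_len(3L), function(i)
    deriveCutoff(norms[i, ], rounding), numeric(1)), .MEASUREMENTS)
  new("CutoffSet", sex = sex, cutoffs = cuts, norms = norms,
      rounding = rounding)
}

#' Build a cutoff set from known cutoff values
#'
#' For replicating published tables when the raw reference data are not at
#' hand: wraps given cutoffs in a [CutoffSet-class] with degenerate
#' provenance (the cutoff itself recorded as a zero-SD norm).
#'
#' @param sex `"male"` or `"female"`.
#' @param grip,mass,treadmill Cutoffs in g, mg, s.
#' @return A [CutoffSet-class].
#' @examples
#' fixedCutoffs("male", grip = 131, mass = 708, treadmill = 514)
#' @export
fixedCutoffs <- function(sex, grip, mass, treadmill) {
  cuts <- c(grip = grip, mass = mass, treadmill = treadmill)
  norms <- data.frame(sex = sex, measurement = .MEASUREMENTS,
                      window_lo = NA_real_, window_hi = NA_real_,
                      n = 2L, mean = unname(cuts), sd = 0)
  new("CutoffSet", sex = sex, cutoffs = cuts, norms = norms,
      rounding = "none")
}

#' Express a measurement as percent of the young reference mean
#'
#' @param value Measurement value(s).
#' @param norms Norms `data.frame` from [computeReference()] (mean > 0).
#' @return `100 * value / mean`, in percent.
#' @export
percentOfYoung <- function(value, norms) {
  if (norms$mean <= 0) stop("reference mean must be > 0")
  100 * value / norms$mean
}

#' Normalize grip strength to body weight or hindlimb muscle mass
#'
#' @param record One-row phenotype `data.frame` (or a whole cohort;
#'   vectorized).
#' @param denominator `"body_weight"` (g/g) or `"hindlimb_mass"` (g/mg).
#' @return The ratio(s), with the unit recorded in an attribute `unit`.
#' @export
normalizeGrip <- function(record, denominator = c("body_weight",
                                                  "hindlimb_mass")) {
  denominator <- match.arg(denominator)
  col <- switch(denominator, body_weight = "body_weight_g",
                hindlimb_mass = "hindlimb_mass_mg")
  if (!col %in% names(record) || anyNA(record[[col]]))
    stop(sprintf("missing field '%s' required to normalize grip strength",
                 col))
  den <- record[[col]]
  if (any(den <= 0)) stop(sprintf("'%s' must be > 0", col))
  structure(record$grip_g / den,
            unit = if (denominator == "body_weight") "g/g" else "g/mg")
}

#' Specific force: peak tetanic force per physiological cross-section
#'
#' @param peakForce Peak force in mN.
#' @param pcsa Physiological cross-sectional area in mm^2 (> 0).
#' @return Specific force in mN/mm^2.
#' @export
specificForce <- function(peakForce, pcsa) {
  if (any(pcsa <= 0)) stop("pcsa must be > 0")
  peakForce / pcsa
}
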