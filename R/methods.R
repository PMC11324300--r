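#' @rdname CutoffSet-class
#' @export
setMethod("cutoffValues", "CutoffSet", function(x) x@cutoffs)

#' @rdname CutoffSet-class
#' @export
setMethod("referenceNorms", "CutoffSet", function(x) x@norms)

setMethod("show", "CutoffSet", function(object) {
  cat(sprintf("CutoffSet (%s), young mean - 2 SD%s\n", object@sex,
              if (object@rounding == "integer") ", integer-rounded" else ""))
  for (m in .MEASUREMENTS)
    cat(sprintf("  %-9s %8.2f %s\n", m, object@cutoffs[[m]],
                .MEASUREMENT_UNITS[[m]]))
})

#' @rdname StagedCohort-class
#' @export
setMethod("stageLabels", "StagedCohort", function(x) x@stage)

#' @rdname StagedCohort-class
#' @export
setMethod("patternLabels", "StagedCohort", function(x) x@pattern)

#' @rdname StagedCohort-class
#' @export
setMethod("deficitCounts", "StagedCohort", function(x) x@deficitCount)

#' @rdname StagedCohort-class
#' @export
setMethod("deficitFlags", "StagedCohort", function(x) x@flags)

#' @rdname StagedCohort-class
#' @export
setMethod("ageBrackets", "StagedCohort", function(x) x@bracket)

#' @describeIn StagedCohort-class Flatten to a `data.frame` (input columns
#'   plus flags, counts, stage, pattern, bracket).
#' @export
setMethod("as.data.frame", "StagedCohort", function(x, ...) {
  cbind(x@records, x@flags,
        deficit_count = x@deficitCount, evaluated_count = x@evaluatedCount,
        stage = as.character(x@stage), pattern = as.character(x@pattern),
        bracket = x@bracket)
})

setMethod("show", "StagedCohort", function(object) {
  n <- nrow(object@records)
  old <- object@bracket != "young"
  cat(sprintf("StagedCohort: %d animals (%d old), sex %s, policy '%s'\n",
              n, sum(old), object@cutoffs@sex, object@policy))
  st <- table(object@stage[old], useNA = "ifany")
  cat("  old-animal stages: ",
      paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n",
      sep = "")
})

#' @rdname GroupComparisonResult-class
#' @export
setMethod("decisionPath", "GroupComparisonResult", function(x) x@path)

#' @rdname GroupComparisonResult-class
#' @export
setMethod("pairwiseResults", "GroupComparisonResult", function(x) x@pairwise)

#' @rdname GroupComparisonResult-class
#' @export
setMethod("omnibusResult", "GroupComparisonResult", function(x) x@omnibus)

setMethod("show", "GroupComparisonResult", function(object) {
  cat("GroupComparisonResult\n")
  cat(sprintf("  omnibus: %s, p = %.4g; post hoc: %s\n",
              object@omnibus$test, object@omnibus$p, object@posthoc))
  for (s in object@path) cat("  - ", s, "\n", sep = "")
  sig <- sum(object@pairwise$label == "significant")
  cat(sprintf("  %d of %d pairwise comparisons significant at alpha=%.2g\n",
              sig, nrow(object@pairwise), object@alpha))
})
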