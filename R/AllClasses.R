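#' @import methods
#' @importFrom stats aov anova lm pf pt ptukey pnorm qnorm sd var
#'   shapiro.test kruskal.test wilcox.test cor.test t.test p.adjust
#'   complete.cases rnorm setNames quantile
#' @importFrom utils read.csv write.csv packageVersion
NULL

.MEASUREMENTS <- c("grip", "mass", "treadmill")
.MEASUREMENT_COLS <- c(grip = "grip_g", mass = "hindlimb_mass_mg",
                       treadmill = "treadmill_s")
.MEASUREMENT_UNITS <- c(grip = "g", mass = "mg", treadmill = "s")
.STAGES <- c("NonS", "PS", "S")
.PATTERNS <- c("none", "G", "M", "T", "GM", "GT", "MT", "GMT")

#' Synthetic cohort configuration
#'
#' Parameters of the Gaussian-copula phenotype generator for one sex:
#' young reference means and standard deviations for grip strength (g),
#' hindlimb muscle mass (mg), and treadmill time to exhaustion (s); the
#' old-age brackets with their mean percent declines relative to young and
#' group sizes; the target Spearman correlation matrix among the three
#' measurements; and the treadmill missingness probability.
#'
#' @slot sex `"male"` or `"female"`.
#' @slot youngMean,youngSD Named numeric vectors (`grip`, `mass`,
#'   `treadmill`) giving the young reference marginals in measurement units.
#' @slot oldSD Named numeric vector of within-bracket SDs for old animals
#'   (defaults to `youngSD`; the source data report only group means).
#' @slot youngN Integer, animals in the young group.
#' @slot youngAges Length-2 numeric, age range (months) young ages are drawn
#'   uniformly from.
#' @slot brackets A `data.frame` with columns `label`, `lo`, `hi` (months,
#'   half-open `[lo, hi)`), `n`, and percent-decline columns `grip`, `mass`,
#'   `treadmill` in `[0, 100)`.
#' @slot spearman 3x3 symmetric target Spearman correlation matrix with unit
#'   diagonal, dimnames the three measurements.
#' @slot missTreadmill Probability in `[0, 1)` that an animal's treadmill
#'   time is missing.
#' @slot seed Integer random seed.
#' @seealso [cohortConfig()], [defaultCohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(sex = "character", youngMean = "numeric",
                 youngSD = "numeric", oldSD = "numeric", youngN = "integer",
                 youngAges = "numeric", brackets = "data.frame",
                 spearman = "matrix", missTreadmill = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!(length(object@sex) == 1L && object@sex %in% c("male", "female")))
    msg <- c(msg, "sex must be \"male\" or \"female\"")
  for (s in c("youngMean", "youngSD", "oldSD")) {
    v <- slot(object, s)
    if (!identical(names(v), .MEASUREMENTS))
      msg <- c(msg, sprintf("%s must be named %s", s,
                            paste(.MEASUREMENTS, collapse = ", ")))
  }
  if (any(object@youngSD < 0) || any(object@oldSD < 0))
    msg <- c(msg, "SDs must be >= 0")
  if (any(object@youngMean <= 0))
    msg <- c(msg, "young means must be > 0")
  b <- object@brackets
  need <- c("label", "lo", "hi", "n", .MEASUREMENTS)
  if (!all(need %in% names(b))) {
    msg <- c(msg, sprintf("brackets must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    dec <- as.matrix(b[, .MEASUREMENTS])
    if (any(dec < 0 | dec >= 100))
      msg <- c(msg, "percent declines must lie in [0, 100)")
    if (any(b$n < 1)) msg <- c(msg, "bracket group sizes must be >= 1")
  }
  sp <- object@spearman
  if (!(is.matrix(sp) && all(dim(sp) == 3L)))
    msg <- c(msg, "spearman must be a 3x3 matrix")
  else {
    if (max(abs(sp - t(sp))) > 1e-12)
      msg <- c(msg, "spearman matrix must be symmetric")
    if (any(abs(diag(sp) - 1) > 1e-12))
      msg <- c(msg, "spearman matrix must have unit diagonal")
    off <- sp[upper.tri(sp)]
    if (any(abs(off) >= 1))
      msg <- c(msg, "off-diagonal Spearman targets must lie in (-1, 1)")
  }
  if (object@missTreadmill < 0 || object@missTreadmill >= 1)
    msg <- c(msg, "missTreadmill must lie in [0, 1)")
  if (object@youngN < 2L) msg <- c(msg, "youngN must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Synthetic proteomics configuration
#'
#' Parameters of the protein-abundance generator used to exercise the
#' gene-set trait-correlation screen: universe size, samples per age cohort,
#' gene-set definitions, and which sets carry an injected correlation with
#' which trait in which cohort.
#'
#' @slot nProteins Integer number of protein rows (default 3110, the size of
#'   a typical deep gastrocnemius proteome).
#' @slot nPerCohort Named integer vector (`young`, `old`), samples per cohort.
#' @slot geneSets Named list of character vectors of protein ids.
#' @slot injected A `data.frame` with columns `set`, `trait`,
#'   `strengthYoung`, `strengthOld` (signed, magnitudes in `[0, 1)`).
#' @slot noiseSD Residual abundance SD.
#' @slot seed Integer random seed.
#' @seealso [proteomicsConfig()], [generateProteomics()]
#' @export
setClass("ProteomicsConfig",
  representation(nProteins = "integer", nPerCohort = "integer",
                 geneSets = "list", injected = "data.frame",
                 noiseSD = "numeric", seed = "integer"))

setValidity("ProteomicsConfig", function(object) {
  msg <- character()
  if (object@nProteins < 2L) msg <- c(msg, "nProteins must be >= 2")
  if (!identical(names(object@nPerCohort), c("young", "old")) ||
      any(object@nPerCohort < 3L))
    msg <- c(msg, "nPerCohort must be named young, old with entries >= 3")
  ids <- paste0("P", seq_len(object@nProteins))
  for (nm in names(object@geneSets)) {
    bad <- setdiff(object@geneSets[[nm]], ids)
    if (length(bad))
      msg <- c(msg, sprintf("gene set '%s' references unknown protein id(s): %s",
                            nm, paste(utils::head(bad, 3), collapse = ", ")))
  }
  inj <- object@injected
  need <- c("set", "trait", "strengthYoung", "strengthOld")
  if (nrow(inj)) {
    if (!all(need %in% names(inj)))
      msg <- c(msg, sprintf("injected must have columns %s",
                            paste(need, collapse = ", ")))
    else {
      if (!all(inj$set %in% names(object@geneSets)))
        msg <- c(msg, "injected references an undefined gene set")
      if (!all(inj$trait %in% .MEASUREMENTS))
        msg <- c(msg, "injected trait must be grip, mass or treadmill")
      if (any(abs(c(inj$strengthYoung, inj$strengthOld)) >= 1))
        msg <- c(msg, "injected correlation magnitudes must lie in [0, 1)")
    }
  }
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be > 0")
  if (length(msg)) msg else TRUE
})

#' Sex-specific deficit cutoffs with their reference-norm provenance
#'
#' One cutoff per measurement (grip strength g, hindlimb mass mg, treadmill
#' time s), each equal to the young reference mean minus two standard
#' deviations, together with the reference norms (sex, age window, n, mean,
#' sd) they were derived from.
#'
#' @slot sex `"male"` or `"female"`.
#' @slot cutoffs Named numeric vector (`grip`, `mass`, `treadmill`), the
#'   classification cutoffs actually applied.
#' @slot norms A `data.frame` of reference norms with columns `sex`,
#'   `measurement`, `window_lo`, `window_hi`, `n`, `mean`, `sd`.
#' @slot rounding `"none"` or `"integer"` — whether `cutoffs` were rounded
#'   to the nearest integer unit.
#' @seealso [deriveCutoffs()], [flagDeficits()]
#' @export
setClass("CutoffSet",
  representation(sex = "character", cutoffs = "numeric",
                 norms = "data.frame", rounding = "character"))

setValidity("CutoffSet", function(object) {
  msg <- character()
  if (!(length(object@sex) == 1L && object@sex %in% c("male", "female")))
    msg <- c(msg, "sex must be \"male\" or \"female\"")
  if (!identical(names(object@cutoffs), .MEASUREMENTS))
    msg <- c(msg, "cutoffs must be named grip, mass, treadmill")
  if (!all(c("measurement", "n", "mean", "sd") %in% names(object@norms)))
    msg <- c(msg, "norms must carry measurement, n, mean, sd columns")
  else {
    if (any(object@norms$n < 2)) msg <- c(msg, "each norm needs n >= 2")
    if (any(object@norms$sd < 0)) msg <- c(msg, "norm sd must be >= 0")
    if (any(object@norms$mean <= 0)) msg <- c(msg, "norm mean must be > 0")
    raw <- setNames(object@norms$mean - 2 * object@norms$sd,
                    object@norms$measurement)[.MEASUREMENTS]
    want <- if (identical(object@rounding, "integer")) round(raw) else raw
    if (any(abs(object@cutoffs - want) > 1e-8))
      msg <- c(msg, "cutoffs must equal mean - 2*sd of their norms (after rounding)")
  }
  if (!object@rounding %in% c("none", "integer"))
    msg <- c(msg, "rounding must be \"none\" or \"integer\"")
  if (length(msg)) msg else TRUE
})

#' A staged cohort: per-animal deficit profiles, stages and patterns
#'
#' Pairs each animal's phenotype record with its deficit flags against a
#' [CutoffSet-class], the resulting deficit count, sarcopenia stage (NonS =
#' 0 deficits, PS = 1, S = 2-3), deficit-pattern label (letters G, M, T in
#' fixed order), and age-bracket label.
#'
#' @slot records The input phenotype `data.frame` (one row per animal).
#' @slot flags A `data.frame` of per-criterion flags `G`, `M`, `T`, each in
#'   `deficit` / `no_deficit` / `missing`.
#' @slot deficitCount,evaluatedCount Integer vectors per animal.
#' @slot stage Factor with levels NonS, PS, S (NA under the complete-case
#'   policy for animals with missing criteria).
#' @slot pattern Factor with levels none, G, M, T, GM, GT, MT, GMT.
#' @slot bracket Character age-bracket label per animal.
#' @slot cutoffs The [CutoffSet-class] used.
#' @slot policy `"available"` (classify on evaluated criteria) or
#'   `"complete"` (animals missing any criterion are left unstaged).
#' @seealso [stageCohort()], [prevalenceTable()]
#' @export
setClass("StagedCohort",
  representation(records = "data.frame", flags = "data.frame",
                 deficitCount = "integer", evaluatedCount = "integer",
                 stage = "factor", pattern = "factor", bracket = "character",
                 cutoffs = "CutoffSet", policy = "character"))

setValidity("StagedCohort", function(object) {
  msg <- character()
  n <- nrow(object@records)
  if (nrow(object@flags) != n || length(object@stage) != n ||
      length(object@pattern) != n || length(object@bracket) != n ||
      length(object@deficitCount) != n || length(object@evaluatedCount) != n)
    msg <- c(msg, "per-animal slots must all have one entry per record")
  if (!identical(names(object@flags), c("G", "M", "T")))
    msg <- c(msg, "flags must have columns G, M, T")
  if (any(object@deficitCount > object@evaluatedCount))
    msg <- c(msg, "deficit count cannot exceed evaluated count")
  ok <- !is.na(object@stage)
  want <- cut(object@deficitCount, c(-1, 0, 1, 3), labels = .STAGES)
  if (any(as.character(object@stage[ok]) != as.character(want[ok])))
    msg <- c(msg, "stage inconsistent with deficit count (0=NonS, 1=PS, 2-3=S)")
  if (!object@policy %in% c("available", "complete"))
    msg <- c(msg, "policy must be \"available\" or \"complete\"")
  if (length(msg)) msg else TRUE
})

#' Result of one multi-group comparison through the decision tree
#'
#' Records the full decision path of a Shapiro-Wilk gated comparison:
#' per-group normality tests, the omnibus test chosen (one-way ANOVA or
#' Kruskal-Wallis), the post hoc procedure (Fisher LSD when the ANOVA p is
#' below the trend threshold, Tukey HSD otherwise, Dunn after
#' Kruskal-Wallis), and every pairwise comparison with its significance
#' label.
#'
#' @slot normality `data.frame` with columns `group`, `W`, `p`.
#' @slot omnibus Named list: `test`, `statistic`, `df`, `p` (plus `MSE` and
#'   `df_resid` for ANOVA).
#' @slot posthoc Name of the pairwise procedure used.
#' @slot pairwise `data.frame` with columns `group1`, `group2`, `estimate`,
#'   `statistic`, `p`, `label` (significant / trend / ns).
#' @slot path Character vector tracing the rules that fired, in order.
#' @slot alpha,trend The significance and trend thresholds used.
#' @seealso [compareGroups()]
#' @export
setClass("GroupComparisonResult",
  representation(normality = "data.frame", omnibus = "list",
                 posthoc = "character", pairwise = "data.frame",
                 path = "character", alpha = "numeric", trend = "numeric"))

setValidity("GroupComparisonResult", function(object) {
  msg <- character()
  pw <- object@pairwise
  if (nrow(pw)) {
    want <- ifelse(pw$p < object@alpha, "significant",
                   ifelse(pw$p < object@trend, "trend", "ns"))
    if (any(pw$label != want))
      msg <- c(msg, "pairwise labels inconsistent with p and thresholds")
  }
  if (object@trend <= object@alpha)
    msg <- c(msg, "trend threshold must exceed alpha")
  if (length(msg)) msg else TRUE
})
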