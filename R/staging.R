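#' Flag deficits against sex-specific cutoffs
#'
#' A deficit means strictly below the cutoff; a value exactly at the cutoff
#' is not a deficit; a missing measurement yields a `missing` flag and is
#' never counted as a deficit.
#'
#' @param cohort Phenotype `data.frame` (one row per animal); all rows must
#'   match the cutoff set's sex.
#' @param cutoffs A [CutoffSet-class].
#' @return A `data.frame` with character columns `G`, `M`, `T` (each
#'   `deficit` / `no_deficit` / `missing`) and integer columns
#'   `deficit_count`, `evaluated_count`.
#' @export
flagDeficits <- function(cohort, cutoffs) {
  validObject(cutoffs)
  if (any(cohort$sex != cutoffs@sex))
    stop(sprintf("cohort contains non-%s animals; cutoffs are sex-specific",
                 cutoffs@sex))
  flag1 <- function(vals, cut) {
    ifelse(is.na(vals), "missing",
           ifelse(vals < cut, "deficit", "no_deficit"))
  }
  fl <- data.frame(
    G = flag1(cohort$grip_g, cutoffs@cutoffs[["grip"]]),
    M = flag1(cohort$hindlimb_mass_mg, cutoffs@cutoffs[["mass"]]),
    T = flag1(cohort$treadmill_s, cutoffs@cutoffs[["treadmill"]]),
    stringsAsFactors = FALSE)
  m <- as.matrix(fl)
  fl$deficit_count <- as.integer(rowSums(m == "deficit"))
  fl$evaluated_count <- as.integer(rowSums(m != "missing"))
  fl
}

#' Classify sarcopenia stage from a deficit profile
#'
#' Zero deficits is non-sarcopenic (NonS), one is probable sarcopenia (PS),
#' two or three is sarcopenia (S). Under the default `available` policy an
#' animal is staged on whatever criteria were evaluated; under the
#' `complete` policy animals missing any criterion are left unstaged (`NA`)
#' and reported separately.
#'
#' @param deficitCount,evaluatedCount Integer vectors (from
#'   [flagDeficits()]).
#' @param policy `"available"` or `"complete"`.
#' @return Factor with levels `NonS`, `PS`, `S`.
#' @export
classifyStage <- function(deficitCount, evaluatedCount,
                          policy = c("available", "complete")) {
  policy <- match.arg(policy)
  if (any(evaluatedCount == 0L))
    stop("unclassifiable: animal(s) with no evaluated criteria")
  stage <- cut(deficitCount, breaks = c(-1, 0, 1, 3), labels = .STAGES)
  if (policy == "complete") stage[evaluatedCount < 3L] <- NA
  stage
}

#' Deficit-pattern label
#'
#' Concatenates the failed-criterion letters in the fixed order G (grip),
#' M (mass), T (treadmill); an empty deficit set is labelled `none`.
#'
#' @param flags `data.frame` with columns `G`, `M`, `T` as from
#'   [flagDeficits()].
#' @return Factor with levels `none, G, M, T, GM, GT, MT, GMT`.
#' @export
patternLabel <- function(flags) {
  m <- as.matrix(flags[, c("G", "M", "T")]) == "deficit"
  lab <- apply(m, 1L, function(r) paste(c("G", "M", "T")[r], collapse = ""))
  lab[lab == ""] <- "none"
  factor(lab, levels = .PATTERNS)
}

#' Default old-age brackets
#'
#' Males: 23-24, 25-26, 27-28, 29-30, and beyond-30 months; females: a
#' single 27-28 month bracket.
#'
#' @param sex `"male"` or `"female"`.
#' @return `data.frame` with columns `label`, `lo`, `hi` (months, half-open
#'   intervals `[lo, hi)`).
#' @export
defaultBrackets <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male")
    data.frame(label = c("23-24", "25-26", "27-28", "29-30", ">30"),
               lo = c(23, 25, 27, 29, 31), hi = c(25, 27, 29, 31, Inf))
  else
    data.frame(label = "27-28", lo = 27, hi = 29)
}

#' Assign an age-bracket label
#'
#' Animals younger than the first old bracket are labelled `young`; an age
#' falling in a gap between brackets (or beyond the last finite bracket) is
#' a configuration error.
#'
#' @param ageMonths Numeric vector of ages in months.
#' @param brackets Bracket `data.frame` (see [defaultBrackets()]).
#' @return Character vector of bracket labels.
#' @export
assignAgeBracket <- function(ageMonths, brackets) {
  o <- order(brackets$lo)
  brackets <- brackets[o, ]
  if (nrow(brackets) > 1L &&
      any(brackets$lo[-1] < brackets$hi[-nrow(brackets)] - 1e-9))
    stop("brackets must be disjoint and ordered")
  lab <- rep(NA_character_, length(ageMonths))
  lab[ageMonths < brackets$lo[1]] <- "young"
  for (i in seq_len(nrow(brackets))) {
    inB <- ageMonths >= brackets$lo[i] & ageMonths < brackets$hi[i]
    lab[inB] <- brackets$label[i]
  }
  if (anyNA(lab))
    stop(sprintf("age(s) %s fall in a gap of the bracket configuration",
                 paste(unique(ageMonths[is.na(lab)]), collapse = ", ")))
  lab
}

#' Stage a cohort against its cutoffs
#'
#' Runs [flagDeficits()], [classifyStage()], [patternLabel()] and
#' [assignAgeBracket()] over a phenotype table and bundles the result.
#'
#' @param cohort Phenotype `data.frame`.
#' @param cutoffs A [CutoffSet-class] matching the cohort's sex.
#' @param brackets Bracket `data.frame`; default per sex.
#' @param policy Missing-data policy, see [classifyStage()].
#' @return A [StagedCohort-class].
#' @examples
#' cohort <- generateCohort(defaultCohortConfig("male"))
#' cuts <- deriveCutoffs(cohort, "male")
#' staged <- stageCohort(cohort, cuts)
#' prevalenceTable(staged)
#' @export
stageCohort <- function(cohort, cutoffs,
                        brackets = defaultBrackets(cutoffs@sex),
                        policy = c("available", "complete")) {
  policy <- match.arg(policy)
  fl <- flagDeficits(cohort, cutoffs)
  stage <- classifyStage(fl$deficit_count, fl$evaluated_count, policy)
  new("StagedCohort", records = cohort,
      flags = fl[, c("G", "M", "T")],
      deficitCount = fl$deficit_count, evaluatedCount = fl$evaluated_count,
      stage = stage, pattern = patternLabel(fl),
      bracket = assignAgeBracket(cohort$age_months, brackets),
      cutoffs = cutoffs, policy = policy)
}

#' Prevalence of sarcopenia stages and deficit patterns
#'
#' Tabulates, per old-age bracket or pooled over all old animals, the count
#' and percentage of each stage (NonS / PS / S) and each deficit pattern.
#' Percentages are computed against the row's staged n and reported to one
#' decimal. Young animals are excluded; animals left unstaged under the
#' `complete` policy are counted in `n_unstaged`.
#'
#' @param staged A [StagedCohort-class].
#' @param by `"bracket"` (default) or `"pooled"`.
#' @return A `data.frame` with one row per bracket (plus a pooled row when
#'   `by = "bracket"`), columns `bracket`, `n`, `n_unstaged`, then
#'   `<stage>_n` / `<stage>_pct` and `<pattern>_n` / `<pattern>_pct`.
#' @export
prevalenceTable <- function(staged, by = c("bracket", "pooled")) {
  by <- match.arg(by)
  old <- staged@bracket != "young"
  if (!any(old)) stop("no old animals to tabulate")
  rowFor <- function(idx, label) {
    st <- staged@stage[idx]; pt <- staged@pattern[idx]
    unst <- sum(is.na(st))
    st <- st[!is.na(st)]; pt <- pt[!is.na(staged@stage[idx])]
    n <- length(st)
    if (n == 0L) stop(sprintf("bracket '%s' has no staged animals", label))
    out <- data.frame(bracket = label, n = n, n_unstaged = unst)
    for (s in .STAGES) {
      out[[paste0(s, "_n")]] <- sum(st == s)
      out[[paste0(s, "_pct")]] <- round(100 * sum(st == s) / n, 1)
    }
    for (p in .PATTERNS) {
      out[[paste0(p, "_n")]] <- sum(pt == p)
      out[[paste0(p, "_pct")]] <- round(100 * sum(pt == p) / n, 1)
    }
    out
  }
  if (by == "pooled") return(rowFor(which(old), "pooled"))
  labs <- unique(staged@bracket[old])
  labs <- labs[order(match(labs, staged@bracket))]
  rows <- lapply(labs, function(b) rowFor(which(staged@bracket == b), b))
  rbind(do.call(rbind, rows), rowFor(which(old), "pooled"))
}

#' Build a cohort with prescribed deficit-pattern counts
#'
#' Constructs a phenotype table of old animals whose deficit patterns
#' against the given cutoffs reproduce exact pattern counts — useful for
#' replicating published prevalence tables from their reported breakdown.
#' Deficit measurements are placed 10 percent below the cutoff,
#' non-deficit measurements 10 percent above.
#'
#' @param counts Named integer vector over patterns
#'   (`none, G, M, T, GM, GT, MT, GMT`); absent names mean zero.
#' @param cutoffs A [CutoffSet-class].
#' @param ageMonths Age assigned to every animal (default 24).
#' @return A phenotype `data.frame` (one row per animal).
#' @export
patternFixtureCohort <- function(counts, cutoffs, ageMonths = 24) {
  counts <- counts[counts > 0]
  stopifnot(all(names(counts) %in% .PATTERNS))
  pats <- rep(names(counts), counts)
  has <- function(letter) grepl(letter, pats, fixed = TRUE)
  val <- function(letter, m) {
    cut <- cutoffs@cutoffs[[m]]
    ifelse(has(letter), 0.9 * cut, 1.1 * cut)
  }
  data.frame(
    animal_id = sprintf("FX%04d", seq_along(pats)), sex = cutoffs@sex,
    age_months = ageMonths, grip_g = val("G", "grip"),
    hindlimb_mass_mg = val("M", "mass"), treadmill_s = val("T", "treadmill"),
    body_weight_g = 30, stringsAsFactors = FALSE)
}
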