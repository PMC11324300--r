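#' Per-protein trait associations by cohort
#'
#' Ordinary least-squares regression of each protein's abundance on a trait,
#' separately within each age cohort: slope, t statistic and two-sided p per
#' protein x cohort x trait. Missing abundances are dropped pairwise. The
#' per-protein summary carried into the gene-set screen is the t statistic,
#' making the screen invariant to per-protein abundance scale.
#'
#' @param x A [SummarizedExperiment::SummarizedExperiment] from
#'   [generateProteomics()] (assay `abundance`, colData with `cohort` and
#'   trait columns), or a numeric matrix (proteins x samples) with `traits`
#'   supplied.
#' @param traits `data.frame` with a `cohort` column and the trait columns,
#'   one row per sample (ignored when `x` is a SummarizedExperiment).
#' @param traitNames Traits to test (default all of grip, mass, treadmill
#'   present).
#' @param cohorts Cohort labels to test (default all present).
#' @return `data.frame` with columns `protein`, `cohort`, `trait`, `slope`,
#'   `t`, `p`, `n`.
#' @export
perProteinAssociation <- function(x, traits = NULL,
                                  traitNames = NULL, cohorts = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    traits <- as.data.frame(SummarizedExperiment::colData(x))
    mat <- SummarizedExperiment::assay(x, "abundance")
  } else mat <- as.matrix(x)
  stopifnot(!is.null(traits), "cohort" %in% names(traits),
            nrow(traits) == ncol(mat))
  if (is.null(traitNames))
    traitNames <- intersect(.MEASUREMENTS, names(traits))
  if (is.null(cohorts)) cohorts <- unique(traits$cohort)
  out <- list()
  for (co in cohorts) {
    idx <- which(traits$cohort == co)
    if (length(idx) < 3L)
      stop(sprintf("cohort '%s' has fewer than 3 samples", co))
    for (tr in traitNames) {
      tv <- traits[idx, tr]
      if (anyNA(tv)) stop(sprintf("trait '%s' missing in cohort '%s'",
                                  tr, co))
      if (var(tv) == 0)
        stop(sprintf("degenerate trait: '%s' is constant in cohort '%s'",
                     tr, co))
      out[[paste(co, tr)]] <- .olsByRow(mat[, idx, drop = FALSE], tv, co, tr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.olsByRow <- function(mat, x, cohort, trait, tCap = 1e8) {
  if (anyNA(mat)) {
    rows <- lapply(seq_len(nrow(mat)), function(i) {
      ok <- !is.na(mat[i, ])
      .olsOne(mat[i, ok], x[ok])
    })
    res <- do.call(rbind, rows)
  } else {
    n <- length(x)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    yc <- mat - rowMeans(mat)
    sxy <- as.vector(yc %*% xc)
    slope <- sxy / sxx
    syy <- rowSums(yc^2)
    r <- sxy / sqrt(sxx * syy)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
    res <- cbind(slope = slope, t = tstat,
                 p = 2 * pt(-abs(tstat), n - 2), n = n)
  }
  res[, "t"] <- pmin(pmax(res[, "t"], -tCap), tCap)
  res[, "p"][is.na(res[, "p"])] <- 1   # zero-variance protein rows
  data.frame(protein = rownames(mat), cohort = cohort, trait = trait,
             res, row.names = NULL, stringsAsFactors = FALSE)
}

.olsOne <- function(y, x, tCap = 1e8) {
  n <- length(y)
  if (n < 3L) return(c(slope = NA, t = 0, p = 1, n = n))
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  slope <- sxy / sxx
  if (syy == 0) return(c(slope = slope, t = 0, p = 1, n = n))
  r <- min(max(sxy / sqrt(sxx * syy), -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(max(1 - r^2, 0))
  tstat <- min(max(tstat, -tCap), tCap)
  c(slope = slope, t = tstat, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Competitive gene-set test on per-protein t statistics
#'
#' Asks whether the set's per-protein trait-association t statistics differ
#' from those of all proteins outside the set, by a two-sided Wilcoxon
#' rank-sum test. Direction is the sign of the in-set minus out-of-set
#' median t.
#'
#' @param associations `data.frame` from [perProteinAssociation()] restricted
#'   to one cohort and one trait (columns `protein`, `t`).
#' @param members Character vector of set member protein ids; ids absent
#'   from the universe are dropped (with a message when `verbose`).
#' @param verbose Report dropped identifiers.
#' @return List with `direction` (+1/-1), `p`, `nIn`, `nOut`.
#' @export
competitiveSetTest <- function(associations, members, verbose = FALSE) {
  stopifnot(all(c("protein", "t") %in% names(associations)))
  if (anyDuplicated(associations$protein))
    stop("associations must cover one cohort and one trait (duplicated protein ids found)")
  inSet <- associations$protein %in% members
  dropped <- length(setdiff(members, associations$protein))
  if (verbose && dropped)
    message(sprintf("%d set member(s) not in the measured universe, dropped",
                    dropped))
  nIn <- sum(inSet); nOut <- sum(!inSet)
  if (nIn < 2L)
    stop("untestable set: fewer than 2 measured members")
  if (nOut == 0L)
    stop("untestable set: set covers the whole measured universe")
  tIn <- associations$t[inSet]; tOut <- associations$t[!inSet]
  w <- suppressWarnings(wilcox.test(tIn, tOut, exact = FALSE))
  dir <- sign(stats::median(tIn) - stats::median(tOut))
  if (dir == 0) dir <- 1
  list(direction = dir, p = w$p.value, nIn = nIn, nOut = nOut)
}

#' Benjamini-Hochberg q values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return q values, same order as the input.
#' @export
bhFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Main-effect screen: gene sets consistent across age cohorts
#'
#' For each gene set, runs the competitive test within the young and the old
#' cohort. Sets whose direction agrees in both cohorts get a combined p by
#' Stouffer's method (equal weights, directional z from each two-sided p);
#' opposite-direction sets are excluded from candidacy. BH q values are
#' computed across the combined p of all same-direction sets, and the
#' main-effect flag marks q below the threshold. The top contributors per
#' set are its 5 members with the largest |t| averaged over the two cohorts.
#'
#' @param young,old `data.frame`s from [perProteinAssociation()] for one
#'   trait, one per cohort, over the same protein universe.
#' @param geneSets Named list of character vectors of protein ids.
#' @param qThreshold FDR threshold for the main-effect flag (default 0.05).
#' @return `data.frame` with one row per testable set: `set`, `direction`
#'   (`"+"`/`"-"`/`"discordant"`), `nIn`, `pYoung`, `pOld`, `pCombined`,
#'   `q`, `mainEffect`, `topContributors` (comma-separated, <= 5 ids).
#' @examples
#' sets <- list(S1 = paste0("P", 1:30))
#' cfg <- proteomicsConfig(nProteins = 300, geneSets = sets,
#'   injected = data.frame(set = "S1", trait = "mass",
#'                         strengthYoung = 0.6, strengthOld = 0.6))
#' se <- generateProteomics(cfg)
#' assoc <- perProteinAssociation(se, traitNames = "mass")
#' mainEffectScreen(assoc[assoc$cohort == "young", ],
#'                  assoc[assoc$cohort == "old", ], sets)
#' @export
mainEffectScreen <- function(young, old, geneSets, qThreshold = 0.05) {
  if (!setequal(young$protein, old$protein))
    stop("young and old association tables must cover the same universe")
  old <- old[match(young$protein, old$protein), ]
  rows <- lapply(names(geneSets), function(nm) {
    members <- geneSets[[nm]]
    ry <- competitiveSetTest(young, members)
    ro <- competitiveSetTest(old, members)
    same <- ry$direction == ro$direction
    if (same) {
      zy <- ry$direction * qnorm(1 - ry$p / 2)
      zo <- ro$direction * qnorm(1 - ro$p / 2)
      z <- (zy + zo) / sqrt(2)
      pc <- 2 * pnorm(-abs(z))
      dir <- if (ry$direction > 0) "+" else "-"
    } else {
      pc <- NA_real_
      dir <- "discordant"
    }
    inIdx <- young$protein %in% members
    meanAbsT <- (abs(young$t[inIdx]) + abs(old$t[inIdx])) / 2
    top <- young$protein[inIdx][order(-meanAbsT)]
    data.frame(set = nm, direction = dir, nIn = ry$nIn,
               pYoung = ry$p, pOld = ro$p, pCombined = pc,
               topContributors = paste(utils::head(top, 5L),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  cand <- !is.na(res$pCombined)
  res$q[cand] <- bhFDR(res$pCombined[cand])
  res$mainEffect <- !is.na(res$q) & res$q < qThreshold
  res[, c("set", "direction", "nIn", "pYoung", "pOld", "pCombined", "q",
          "mainEffect", "topContributors")]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param geneSets Named list of character vectors.
#' @param path Output path.
#' @export
writeGMT <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, "na", geneSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
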