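#' Map a Spearman target to the latent Pearson correlation
#'
#' For a Gaussian copula, a latent Pearson correlation of
#' \eqn{2 \sin(\pi \rho_s / 6)} yields an observed Spearman correlation of
#' \eqn{\rho_s} on the (continuous) margins. Used elementwise to calibrate
#' the generator's latent multivariate normal so empirical rank correlations
#' match the configured targets.
#'
#' @param rhoS Spearman correlation(s), each with `|rhoS| < 1`; a scalar,
#'   vector, or square matrix (diagonal entries of exactly 1 are passed
#'   through).
#' @return The latent Pearson correlation(s), same shape as the input.
#' @examples
#' spearmanToLatent(0.48)  # ~0.4983
#' @export
spearmanToLatent <- function(rhoS) {
  off <- if (is.matrix(rhoS)) rhoS[row(rhoS) != col(rhoS)] else rhoS
  if (any(abs(off) >= 1))
    stop("Spearman correlations must satisfy |rho| < 1")
  out <- 2 * sin(pi * rhoS / 6)
  if (is.matrix(rhoS)) diag(out) <- diag(rhoS)
  out
}

#' Construct a synthetic cohort configuration
#'
#' @param sex `"male"` or `"female"`.
#' @param youngMean,youngSD Named numeric vectors (`grip`, `mass`,
#'   `treadmill`): young reference means and SDs in g / mg / s.
#' @param brackets `data.frame` with columns `label`, `lo`, `hi` (months,
#'   half-open), `n`, and percent declines `grip`, `mass`, `treadmill`.
#' @param spearman 3x3 target Spearman correlation matrix (defaults to the
#'   moderate positive inter-trait structure seen in old mice, grip-mass
#'   0.48).
#' @param oldSD Within-bracket SDs for old animals; defaults to `youngSD`.
#' @param youngN Young group size.
#' @param youngAges Age range (months) for the young group.
#' @param missTreadmill Treadmill missingness probability.
#' @param seed Integer random seed.
#' @return A [CohortConfig-class].
#' @seealso [defaultCohortConfig()] for ready-made study-like settings.
#' @export
cohortConfig <- function(sex, youngMean, youngSD, brackets,
                         spearman = defaultSpearmanTarget(),
                         oldSD = youngSD, youngN = 30L,
                         youngAges = c(4, 9), missTreadmill = 0.19,
                         seed = 1L) {
  dimnames(spearman) <- list(.MEASUREMENTS, .MEASUREMENTS)
  new("CohortConfig", sex = sex,
      youngMean = youngMean[.MEASUREMENTS], youngSD = youngSD[.MEASUREMENTS],
      oldSD = oldSD[.MEASUREMENTS], youngN = as.integer(youngN),
      youngAges = youngAges, brackets = brackets, spearman = spearman,
      missTreadmill = missTreadmill, seed = as.integer(seed))
}

#' @rdname cohortConfig
#' @export
defaultSpearmanTarget <- function() {
  sp <- matrix(0.30, 3, 3, dimnames = list(.MEASUREMENTS, .MEASUREMENTS))
  sp["grip", "mass"] <- sp["mass", "grip"] <- 0.48
  diag(sp) <- 1
  sp
}

#' Study-like default generator settings
#'
#' Young reference marginals are free parameters of the generator, chosen so
#' that mean minus two SDs reproduces the published integer cutoffs (males
#' 131 g / 708 mg / 514 s, females 126 g / 621 mg / 576 s); they are not
#' themselves published values. Male bracket mean declines interpolate
#' linearly between the published endpoints (21/15/20 percent for
#' grip/mass/treadmill at 23-24 months; 34/30/51 percent beyond 30 months);
#' females get a single 27-28 month bracket with 13 percent declines across
#' the board. Treadmill missingness defaults to 0.19, the fraction implied
#' by the study's smaller treadmill sample sizes.
#'
#' @param sex `"male"` or `"female"`.
#' @param n Animals per old bracket (male default 25; the female default
#'   bracket holds 33).
#' @param seed Integer random seed.
#' @return A [CohortConfig-class].
#' @examples
#' cfg <- defaultCohortConfig("male", seed = 7)
#' cohort <- generateCohort(cfg)
#' head(cohort)
#' @export
defaultCohortConfig <- function(sex = c("male", "female"), n = NULL,
                                seed = 1L) {
  sex <- match.arg(sex)
  if (sex == "male") {
    if (is.null(n)) n <- 25L
    br <- data.frame(
      label = c("23-24", "25-26", "27-28", "29-30", ">30"),
      lo = c(23, 25, 27, 29, 31), hi = c(25, 27, 29, 31, Inf), n = n,
      grip = seq(21, 34, length.out = 5),
      mass = seq(15, 30, length.out = 5),
      treadmill = seq(20, 51, length.out = 5))
    cohortConfig("male",
                 youngMean = c(grip = 165, mass = 850, treadmill = 750),
                 youngSD = c(grip = 17, mass = 71, treadmill = 118),
                 brackets = br, youngAges = c(4, 9), seed = seed)
  } else {
    if (is.null(n)) n <- 33L
    br <- data.frame(label = "27-28", lo = 27, hi = 29, n = n,
                     grip = 13, mass = 13, treadmill = 13)
    cohortConfig("female",
                 youngMean = c(grip = 160, mass = 745, treadmill = 800),
                 youngSD = c(grip = 17, mass = 62, treadmill = 112),
                 brackets = br, youngN = 20L, youngAges = c(6, 7),
                 seed = seed)
  }
}

.latentCorrelation <- function(spearman) {
  lat <- spearmanToLatent(spearman)
  ev <- eigen(lat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    off <- which(upper.tri(lat), arr.ind = TRUE)
    pairs <- apply(off, 1L, function(ij)
      sprintf("%s-%s=%.3f", rownames(lat)[ij[1]], colnames(lat)[ij[2]],
              lat[ij[1], ij[2]]))
    stop("latent correlation matrix is not positive definite (entries: ",
         paste(pairs, collapse = ", "), ")")
  }
  lat
}

#' Generate a synthetic phenotype cohort
#'
#' Draws, for the young group and each configured old bracket, latent
#' multivariate normal vectors with the copula-calibrated correlation (see
#' [spearmanToLatent()]), then maps each margin to a normal with mean
#' `youngMean * (1 - decline/100)` and the configured SD. Young animals are
#' drawn with zero decline. Treadmill values are set missing with the
#' configured probability. Draws below 0.1 measurement units are truncated
#' to that floor, with a warning reporting the truncation rate.
#'
#' @param config A [CohortConfig-class].
#' @param seed Overrides `config@seed` if given.
#' @return A `data.frame` with columns `animal_id`, `sex`, `age_months`,
#'   `grip_g`, `hindlimb_mass_mg`, `treadmill_s`, `body_weight_g`.
#' @export
generateCohort <- function(config, seed = config@seed) {
  validObject(config)
  lat <- .latentCorrelation(config@spearman)
  set.seed(seed)
  groups <- rbind(
    data.frame(label = "young", lo = config@youngAges[1],
               hi = config@youngAges[2], n = config@youngN,
               grip = 0, mass = 0, treadmill = 0),
    config@brackets)
  out <- vector("list", nrow(groups))
  truncated <- 0L; total <- 0L
  for (g in seq_len(nrow(groups))) {
    gr <- groups[g, ]
    z <- MASS::mvrnorm(gr$n, mu = rep(0, 3), Sigma = lat)
    z <- matrix(z, ncol = 3)
    sds <- if (gr$label == "young") config@youngSD else config@oldSD
    mus <- config@youngMean *
      (1 - unlist(gr[.MEASUREMENTS]) / 100)
    vals <- sweep(sweep(z, 2L, sds, `*`), 2L, mus, `+`)
    truncated <- truncated + sum(vals < 0.1)
    total <- total + length(vals)
    vals[vals < 0.1] <- 0.1
    hi <- if (is.finite(gr$hi)) gr$hi else gr$lo + 2
    ages <- stats::runif(gr$n, gr$lo, hi)
    bw <- stats::rnorm(gr$n, if (config@sex == "male") 32 else 27, 3)
    bw[bw < 0.1] <- 0.1
    out[[g]] <- data.frame(
      group = gr$label, age_months = round(ages, 1),
      grip_g = vals[, 1], hindlimb_mass_mg = vals[, 2],
      treadmill_s = vals[, 3], body_weight_g = round(bw, 2))
  }
  df <- do.call(rbind, out)
  miss <- stats::runif(nrow(df)) < config@missTreadmill
  df$treadmill_s[miss] <- NA_real_
  if (truncated > 0)
    warning(sprintf("%d of %d draws (%.2f%%) truncated at the 0.1-unit floor",
                    truncated, total, 100 * truncated / total))
  data.frame(
    animal_id = sprintf("%s%04d", toupper(substr(config@sex, 1, 1)),
                        seq_len(nrow(df))),
    sex = config@sex, age_months = df$age_months,
    grip_g = df$grip_g, hindlimb_mass_mg = df$hindlimb_mass_mg,
    treadmill_s = df$treadmill_s, body_weight_g = df$body_weight_g,
    stringsAsFactors = FALSE)
}

#' Construct a synthetic proteomics configuration
#'
#' @param nProteins Number of protein rows (default 3110).
#' @param nPerCohort Named integer vector (`young`, `old`).
#' @param geneSets Named list of character vectors of protein ids
#'   (`"P1"` ... `"P<nProteins>"`).
#' @param injected `data.frame` with columns `set`, `trait`,
#'   `strengthYoung`, `strengthOld`; rows name the gene sets that carry a
#'   signed trait correlation in each cohort. Default: none.
#' @param noiseSD Residual abundance SD (default 1).
#' @param seed Integer random seed.
#' @return A [ProteomicsConfig-class].
#' @export
proteomicsConfig <- function(nProteins = 3110L,
                             nPerCohort = c(young = 40L, old = 40L),
                             geneSets = list(),
                             injected = data.frame(
                               set = character(), trait = character(),
                               strengthYoung = numeric(),
                               strengthOld = numeric()),
                             noiseSD = 1, seed = 1L) {
  new("ProteomicsConfig", nProteins = as.integer(nProteins),
      nPerCohort = setNames(as.integer(nPerCohort), c("young", "old")),
      geneSets = geneSets, injected = injected, noiseSD = noiseSD,
      seed = as.integer(seed))
}

#' Generate a synthetic protein-abundance matrix tied to phenotype traits
#'
#' Background proteins are trait-independent Gaussian noise. Each protein in
#' an injected gene set receives, within each cohort, an added
#' `strength * z` term where `z` is the configured trait standardized within
#' that cohort, so its abundance-trait correlation is
#' \eqn{s/\sqrt{s^2+\sigma^2}} for strength `s` and noise SD \eqn{\sigma}.
#'
#' @param config A [ProteomicsConfig-class].
#' @param traits `data.frame` with one row per sample: a `cohort` column
#'   (`"young"` / `"old"`, counts matching `config@nPerCohort`) and numeric
#'   columns `grip`, `mass`, `treadmill`. If `NULL`, traits are simulated
#'   from [defaultCohortConfig()] marginals.
#' @param seed Overrides `config@seed` if given.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `abundance` (proteins x samples), the traits and cohort labels in
#'   `colData`, and the gene sets in `metadata(x)$geneSets`.
#' @export
generateProteomics <- function(config, traits = NULL, seed = config@seed) {
  validObject(config)
  set.seed(seed)
  nY <- config@nPerCohort[["young"]]; nO <- config@nPerCohort[["old"]]
  if (is.null(traits)) traits <- .simulateTraits(nY, nO)
  stopifnot(is.data.frame(traits),
            all(c("cohort", .MEASUREMENTS) %in% names(traits)))
  if (sum(traits$cohort == "young") != nY ||
      sum(traits$cohort == "old") != nO)
    stop("trait table cohort counts must match config@nPerCohort")
  if (anyNA(traits[, .MEASUREMENTS]))
    stop("traits must be available for every sample")
  nS <- nY + nO
  ids <- paste0("P", seq_len(config@nProteins))
  mat <- matrix(stats::rnorm(config@nProteins * nS, sd = config@noiseSD),
                nrow = config@nProteins,
                dimnames = list(ids, sprintf("S%03d", seq_len(nS))))
  inj <- config@injected
  for (k in seq_len(nrow(inj))) {
    members <- config@geneSets[[inj$set[k]]]
    for (cohort in c("young", "old")) {
      s <- if (cohort == "young") inj$strengthYoung[k] else inj$strengthOld[k]
      if (s == 0) next
      idx <- which(traits$cohort == cohort)
      z <- scale(traits[idx, inj$trait[k]])[, 1]
      mat[members, idx] <- mat[members, idx] +
        matrix(s * z, nrow = length(members), ncol = length(idx),
               byrow = TRUE)
    }
  }
  cd <- S4Vectors::DataFrame(traits, row.names = colnames(mat))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat), colData = cd,
    metadata = list(geneSets = config@geneSets, config = config))
}

.simulateTraits <- function(nY, nO) {
  cfgY <- defaultCohortConfig("male")
  lat <- .latentCorrelation(cfgY@spearman)
  mk <- function(n, decline) {
    z <- matrix(MASS::mvrnorm(n, rep(0, 3), lat), ncol = 3)
    sweep(sweep(z, 2L, cfgY@youngSD, `*`), 2L,
          cfgY@youngMean * (1 - decline / 100), `+`)
  }
  y <- mk(nY, c(0, 0, 0)); o <- mk(nO, c(27.5, 22.5, 35.5))
  df <- as.data.frame(rbind(y, o))
  names(df) <- .MEASUREMENTS
  cbind(cohort = rep(c("young", "old"), c(nY, nO)), df)
}
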