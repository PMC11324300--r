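test_that("Spearman-to-latent map follows the Gaussian-copula identity", {
  expect_equal(spearmanToLatent(0), 0)
  expect_equal(spearmanToLatent(0.48), 2 * sin(pi * 0.48 / 6))
  expect_equal(round(spearmanToLatent(0.48), 4), 0.4974)
  # symmetric, and approaches 1 at the boundary
  expect_equal(spearmanToLatent(-0.3), -spearmanToLatent(0.3))
  expect_lt(abs(spearmanToLatent(0.999999) - 1), 1e-5)
  expect_error(spearmanToLatent(1), "rho")
  expect_error(spearmanToLatent(-1.2), "rho")
  m <- defaultSpearmanTarget()
  lat <- spearmanToLatent(m)
  expect_equal(diag(lat), rep(1, 3), ignore_attr = TRUE)
  expect_equal(lat["grip", "mass"], 2 * sin(pi * 0.48 / 6))
})

test_that("cohort generation is deterministic given config and seed", {
  cfg <- defaultCohortConfig("male", n = 50, seed = 42)
  a <- suppressWarnings(generateCohort(cfg))
  b <- suppressWarnings(generateCohort(cfg))
  expect_identical(a, b)
  c <- suppressWarnings(generateCohort(cfg, seed = 43))
  expect_false(identical(a, c))
})

test_that("null configuration recovers independent young-level marginals", {
  br <- data.frame(label = "old", lo = 23, hi = 33, n = 2000,
                   grip = 0, mass = 0, treadmill = 0)
  cfg <- cohortConfig("male",
                      youngMean = c(grip = 165, mass = 850, treadmill = 750),
                      youngSD = c(grip = 17, mass = 71, treadmill = 118),
                      brackets = br, spearman = diag(3), youngN = 2000L,
                      missTreadmill = 0, seed = 7L)
  co <- generateCohort(cfg)
  for (grp in list(co$age_months < 23, co$age_months >= 23)) {
    sub <- co[grp, ]
    expect_lt(abs(mean(sub$grip_g) / 165 - 1), 0.02)
    expect_lt(abs(mean(sub$hindlimb_mass_mg) / 850 - 1), 0.02)
    expect_lt(abs(mean(sub$treadmill_s) / 750 - 1), 0.02)
    expect_lt(abs(sd(sub$grip_g) / 17 - 1), 0.10)
    expect_lt(abs(sd(sub$hindlimb_mass_mg) / 71 - 1), 0.10)
    expect_lt(abs(cor(sub$grip_g, sub$hindlimb_mass_mg,
                      method = "spearman")), 0.05)
    expect_lt(abs(cor(sub$grip_g, sub$treadmill_s,
                      method = "spearman")), 0.05)
  }
})

test_that("configured bracket declines are recovered as percent of young", {
  cfg <- defaultCohortConfig("male", n = 2000, seed = 3)
  cfg@youngN <- 2000L
  co <- suppressWarnings(generateCohort(cfg))
  norms <- lapply(c(grip = "grip", mass = "mass", treadmill = "treadmill"),
                  function(m) computeReference(co, "male", m, c(4, 9)))
  b <- co[co$age_months >= 23 & co$age_months < 25, ]
  expect_lt(abs(mean(percentOfYoung(b$grip_g, norms$grip)) - 79), 2)
  expect_lt(abs(mean(percentOfYoung(b$hindlimb_mass_mg, norms$mass)) - 85), 2)
  expect_lt(abs(mean(percentOfYoung(b$treadmill_s[!is.na(b$treadmill_s)],
                                    norms$treadmill)) - 80), 2)
})

test_that("target Spearman correlations are met within each group", {
  cfg <- defaultCohortConfig("male", seed = 9)
  cfg@youngN <- 5000L
  cfg@missTreadmill <- 0
  co <- suppressWarnings(generateCohort(cfg))
  y <- co[co$age_months < 23, ]
  expect_lt(abs(cor(y$grip_g, y$hindlimb_mass_mg,
                    method = "spearman") - 0.48), 0.05)
  expect_lt(abs(cor(y$grip_g, y$treadmill_s,
                    method = "spearman") - 0.30), 0.05)
  expect_lt(abs(cor(y$hindlimb_mass_mg, y$treadmill_s,
                    method = "spearman") - 0.30), 0.05)
})

test_that("treadmill missingness matches its configured probability", {
  cfg <- defaultCohortConfig("male", n = 500, seed = 5)
  cfg@youngN <- 500L
  co <- suppressWarnings(generateCohort(cfg))
  expect_lt(abs(mean(is.na(co$treadmill_s)) - 0.19), 0.02)
  cfg@missTreadmill <- 0
  co0 <- suppressWarnings(generateCohort(cfg))
  expect_false(anyNA(co0$treadmill_s))
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohortConfig("male",
    youngMean = c(grip = 165, mass = 850, treadmill = 750),
    youngSD = c(grip = -1, mass = 71, treadmill = 118),
    brackets = defaultCohortConfig("male")@brackets), "SD")
  br <- defaultCohortConfig("male")@brackets
  br$grip <- 120
  expect_error(cohortConfig("male",
    youngMean = c(grip = 165, mass = 850, treadmill = 750),
    youngSD = c(grip = 17, mass = 71, treadmill = 118),
    brackets = br), "declines")
  # near-singular Spearman targets give a non-PD latent matrix
  sp <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  cfg <- defaultCohortConfig("male")
  cfg@spearman <- `dimnames<-`(sp, dimnames(cfg@spearman))
  expect_error(generateCohort(cfg), "positive definite")
})

test_that("draws below the physical floor are truncated with a warning", {
  br <- data.frame(label = "old", lo = 23, hi = 25, n = 200,
                   grip = 99, mass = 99, treadmill = 99)
  cfg <- cohortConfig("male",
    youngMean = c(grip = 1, mass = 1, treadmill = 1),
    youngSD = c(grip = 5, mass = 5, treadmill = 5),
    brackets = br, spearman = diag(3), youngN = 10L, seed = 1L)
  expect_warning(co <- generateCohort(cfg), "truncated")
  expect_true(all(co$grip_g >= 0.1))
})

test_that("proteomics generator matches its configuration", {
  cfg <- proteomicsConfig(seed = 2)
  se <- generateProteomics(cfg)
  expect_equal(nrow(se), 3110)
  expect_equal(ncol(se), 80)
  se2 <- generateProteomics(cfg)
  expect_identical(SummarizedExperiment::assay(se),
                   SummarizedExperiment::assay(se2))
  expect_error(proteomicsConfig(nProteins = 100,
    geneSets = list(bad = c("P1", "P999"))), "unknown protein")
})

test_that("injected sets raise trait association above background", {
  sets <- list(S1 = paste0("P", 1:30))
  cfg <- proteomicsConfig(nProteins = 400, geneSets = sets,
    injected = data.frame(set = "S1", trait = "mass",
                          strengthYoung = 0.6, strengthOld = 0.6),
    seed = 8)
  se <- generateProteomics(cfg)
  assoc <- perProteinAssociation(se, traitNames = "mass")
  a <- assoc[assoc$cohort == "old", ]
  inSet <- a$protein %in% sets$S1
  expect_gt(mean(abs(a$t[inSet])), mean(abs(a$t[!inSet])))
  # with no injection the in-set statistics sit at background level
  cfg0 <- proteomicsConfig(nProteins = 400, geneSets = sets, seed = 8)
  a0 <- perProteinAssociation(generateProteomics(cfg0), traitNames = "mass")
  a0 <- a0[a0$cohort == "old", ]
  expect_gt(suppressWarnings(
    wilcox.test(abs(a0$t[a0$protein %in% sets$S1]),
                abs(a0$t[!a0$protein %in% sets$S1]))$p.value), 0.01)
})
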