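toy <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  fit <- anovaOneway(toy)
  o <- oracleAnova(toy)
  expect_equal(fit$F, o$F, tolerance = 1e-10)
  expect_equal(fit$p, o$p, tolerance = 1e-10)
  expect_equal(fit$MSE, o$MSE, tolerance = 1e-10)
  expect_equal(fit$df2, o$df2)
  # identical groups: no between-group signal
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  f0 <- anovaOneway(same)
  expect_lt(abs(f0$F), 1e-12)
  expect_equal(f0$p, 1)
  # two groups: F is the squared pooled t
  g2 <- list(a = c(1.2, 2.5, 3.1, 4), b = c(2, 3.3, 5.2))
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(anovaOneway(g2)$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(anovaOneway(list(a = 1:3, b = 2)), "insufficient")
  expect_error(anovaOneway(list(a = rep(1, 3), b = rep(1, 4))),
               "degenerate")
})

test_that("Fisher LSD equals direct pooled-error t computations", {
  fit <- anovaOneway(toy)
  pw <- fisherLSD(fit)
  o13 <- oracleLSD(toy, "g1", "g3")
  row <- pw[pw$group1 == "g1" & pw$group2 == "g3", ]
  expect_equal(row$statistic, o13$t, tolerance = 1e-10)
  expect_equal(row$p, o13$p, tolerance = 1e-10)
  # equal pair means give p = 1
  same <- anovaOneway(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(5, 6, 7)))
  pwS <- fisherLSD(same)
  expect_equal(pwS$p[pwS$group1 == "a" & pwS$group2 == "b"], 1)
  # with two groups LSD reduces to the pooled two-sample t test
  g2 <- list(a = c(1.2, 2.5, 3.1, 4), b = c(2, 3.3, 5.2))
  pw2 <- fisherLSD(anovaOneway(g2))
  expect_equal(pw2$p, t.test(g2$a, g2$b, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("Tukey HSD matches the stats::TukeyHSD route and dominates LSD", {
  set.seed(20)
  bal <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1))
  fit <- anovaOneway(bal)
  pw <- tukeyPairwise(fit)
  y <- unlist(bal)
  g <- factor(rep(names(bal), lengths(bal)))
  ref <- stats::TukeyHSD(aov(y ~ g))$g
  key <- paste(pw$group2, pw$group1, sep = "-")
  expect_equal(pw$p, unname(ref[key, "p adj"]), tolerance = 1e-8)
  # identical groups: all adjusted p near 1
  same <- anovaOneway(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(tukeyPairwise(same)$p > 0.999))
})

test_that("Tukey adjusted p is never below the unadjusted LSD p", {
  set.seed(21)
  for (rep in 1:40) {
    k <- sample(3:5, 1)
    gs <- setNames(lapply(seq_len(k), function(i)
      rnorm(sample(4:9, 1), mean = rnorm(1))), paste0("g", seq_len(k)))
    fit <- anovaOneway(gs)
    expect_true(all(tukeyPairwise(fit)$p >= fisherLSD(fit)$p - 1e-12))
  }
})

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  gs <- list(a = c(1, 2, 3, 2), b = c(10, 11, 12), c = c(5, 5, 6))
  kw <- kruskalWallisPairwise(gs)
  o <- oracleKW(gs)
  expect_equal(kw$H, o$H, tolerance = 1e-10)
  expect_equal(kw$p, o$p, tolerance = 1e-10)
  expect_error(kruskalWallisPairwise(list(a = rep(2, 3), b = rep(2, 3))),
               "degenerate")
})

test_that("rank-sum pairwise follow-up equals the Wilcoxon test", {
  gs <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(1.5, 2.5, 3.5))
  kw <- kruskalWallisPairwise(gs, pairwise = "ranksum")
  w <- suppressWarnings(wilcox.test(gs$a, gs$b, exact = FALSE,
                                    correct = FALSE))
  row <- kw$pairwise[kw$pairwise$group1 == "a" & kw$pairwise$group2 == "b", ]
  expect_equal(row$p, w$p.value, tolerance = 1e-10)
  # Dunn z agrees with its closed form on two groups with no ties
  kd <- kruskalWallisPairwise(gs[1:2], pairwise = "dunn")
  y <- unlist(gs[1:2]); r <- rank(y); N <- length(y)
  z <- (mean(r[1:3]) - mean(r[4:6])) /
    sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  expect_equal(kd$pairwise$statistic, z, tolerance = 1e-10)
})

test_that("Dunnett comparisons reduce to the t test and match multcomp", {
  set.seed(22)
  g2 <- list(ctl = rnorm(8), trt = rnorm(8, 1))
  d <- dunnettVsControl(g2, "ctl", nMC = 2e5, seed = 1)
  tt <- t.test(g2$trt, g2$ctl, var.equal = TRUE)
  expect_lt(abs(d$p - tt$p.value), 0.01)
  same <- list(ctl = c(1, 2, 3), a = c(1, 2, 3), b = c(1, 2, 3))
  expect_true(all(dunnettVsControl(same, "ctl", nMC = 1e4)$p > 0.99))
  expect_error(dunnettVsControl(g2, "nope"), "control")
  # against the multivariate-t route
  library(multcomp)
  gs <- list(ctl = rnorm(10), a = rnorm(10, 0.8), b = rnorm(10, -0.5),
             c = rnorm(10))
  d3 <- dunnettVsControl(gs, "ctl", nMC = 4e5, seed = 2)
  y <- unlist(gs)
  grp <- factor(rep(names(gs), lengths(gs)), levels = names(gs))
  mc <- summary(glht(aov(y ~ grp), linfct = mcp(grp = "Dunnett")))
  expect_lt(max(abs(d3$p - as.numeric(mc$test$pvalues))), 0.005)
})

test_that("Spearman correlation handles monotone, reversed and missing data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearmanCor(x, x^3)$rho, 1)
  expect_equal(spearmanCor(x, -2 * x + 1)$rho, -1)
  r <- spearmanCor(c(x, NA), c(x^2, 10))
  expect_equal(r$n, 5)
  expect_error(spearmanCor(c(1, 2), c(3, 4)), "3 complete pairs")
})

test_that("two-sample t test honours its contracts and the F identity", {
  x <- c(1, 2, 3)
  expect_equal(twoSampleT(x, x)$p, 1)
  expect_lt(twoSampleT(x, x + 100)$p, 1e-4)
  y <- c(2.5, 3.1, 4.7, 5)
  expect_equal(twoSampleT(x, y)$t^2,
               anovaOneway(list(a = x, b = y))$F, tolerance = 1e-10)
  expect_error(twoSampleT(x, 1), "n >= 2")
  # Welch option
  expect_equal(twoSampleT(x, y, welch = TRUE)$p, t.test(x, y)$p.value)
})

test_that("decision tree takes the ANOVA/LSD path on shifted normal groups", {
  set.seed(23)
  gs <- nullGroups(4, 10, mu = c(0, 0, 0, 2))
  res <- compareGroups(gs)
  expect_equal(omnibusResult(res)$test, "anova")
  expect_equal(res@posthoc, "fisher_lsd")
  pw <- pairwiseResults(res)
  shifted <- pw[pw$group1 == "g4" | pw$group2 == "g4", ]
  expect_true(all(shifted$p < 0.05))
  expect_true(all(shifted$label == "significant"))
})

test_that("decision tree switches to Kruskal-Wallis when normality fails", {
  set.seed(24)
  gs <- list(a = rnorm(15), b = rnorm(15), c = exp(rnorm(15, 0, 1.5)))
  res <- compareGroups(gs)
  expect_equal(omnibusResult(res)$test, "kruskal_wallis")
  expect_match(decisionPath(res)[1], "Kruskal-Wallis")
  expect_true(any(res@normality$p < 0.05))
})

test_that("Tukey branch fires when the omnibus ANOVA shows no trend", {
  set.seed(25)
  gs <- nullGroups(3, 12)
  # regenerate until the null draw lands in the no-trend region
  while (anovaOneway(gs)$p < 0.1) gs <- nullGroups(3, 12)
  res <- compareGroups(gs)
  expect_equal(res@posthoc, "tukey_hsd")
  expect_match(decisionPath(res)[2], "Tukey")
})

test_that("pairwise labels are recomputable from p and the thresholds", {
  set.seed(26)
  for (i in 1:20) {
    gs <- nullGroups(3, 8, mu = rnorm(3, sd = 0.8))
    res <- compareGroups(gs, alpha = 0.05, trend = 0.1)
    pw <- pairwiseResults(res)
    want <- ifelse(pw$p < 0.05, "significant",
                   ifelse(pw$p < 0.1, "trend", "ns"))
    expect_identical(pw$label, want)
  }
})

test_that("identical inputs yield identical comparison results", {
  set.seed(27)
  gs <- nullGroups(4, 10)
  r1 <- compareGroups(gs)
  r2 <- compareGroups(gs)
  expect_identical(pairwiseResults(r1), pairwiseResults(r2))
  expect_identical(decisionPath(r1), decisionPath(r2))
})
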