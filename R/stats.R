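.checkGroups <- function(groups, minN = 3L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  small <- vapply(groups, length, integer(1)) < minN
  if (any(small))
    stop(sprintf("insufficient data: group(s) %s have fewer than %d values",
                 paste(names(groups)[small], collapse = ", "), minN))
  groups
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition over a named list of groups, exposing the
#' pooled mean squared error and residual degrees of freedom for post hoc
#' reuse.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @return List with `F`, `p`, `MSE`, `df1`, `df2`, and per-group `means`
#'   and `ns`.
#' @export
anovaOneway <- function(groups) {
  groups <- .checkGroups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (var(y) == 0) stop("degenerate input: zero variance across all groups")
  tab <- anova(lm(y ~ g))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       MSE = tab$`Mean Sq`[2], df1 = tab$Df[1], df2 = tab$Df[2],
       means = vapply(groups, mean, numeric(1)),
       ns = lengths(groups))
}

.pairGrid <- function(nms) {
  idx <- utils::combn(seq_along(nms), 2L)
  data.frame(group1 = nms[idx[1, ]], group2 = nms[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests using the ANOVA pooled error:
#' \eqn{t = (\bar y_i - \bar y_j)/\sqrt{MSE(1/n_i + 1/n_j)}} on the residual
#' degrees of freedom.
#'
#' @param fit Result of [anovaOneway()] on the same groups.
#' @return `data.frame` with `group1`, `group2`, `estimate` (mean
#'   difference), `statistic` (t), `p`.
#' @export
fisherLSD <- function(fit) {
  pw <- .pairGrid(names(fit$means))
  est <- fit$means[pw$group1] - fit$means[pw$group2]
  se <- sqrt(fit$MSE * (1 / fit$ns[pw$group1] + 1 / fit$ns[pw$group2]))
  tstat <- est / se
  pw$estimate <- unname(est)
  pw$statistic <- unname(tstat)
  pw$p <- unname(2 * pt(-abs(tstat), fit$df2))
  pw
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p for every pair, using the Tukey-Kramer
#' standard error for unequal group sizes.
#'
#' @inheritParams fisherLSD
#' @return `data.frame` as in [fisherLSD()] with adjusted `p`.
#' @export
tukeyPairwise <- function(fit) {
  k <- length(fit$means)
  pw <- .pairGrid(names(fit$means))
  est <- fit$means[pw$group1] - fit$means[pw$group2]
  se <- sqrt(fit$MSE / 2 * (1 / fit$ns[pw$group1] + 1 / fit$ns[pw$group2]))
  q <- abs(est) / se
  pw$estimate <- unname(est)
  pw$statistic <- unname(q)
  pw$p <- unname(ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE))
  pw
}

#' Kruskal-Wallis omnibus test with rank-based pairwise follow-up
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p, followed by
#' unadjusted pairwise comparisons: Dunn's z tests on the pooled mid-ranks
#' (default) or Wilcoxon rank-sum tests.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @param pairwise `"dunn"` or `"ranksum"`.
#' @return List with `H`, `df`, `p`, and a `pairwise` `data.frame`
#'   (`group1`, `group2`, `estimate` = rank-mean difference, `statistic`,
#'   `p`).
#' @export
kruskalWallisPairwise <- function(groups, pairwise = c("dunn", "ranksum")) {
  pairwise <- match.arg(pairwise)
  groups <- .checkGroups(groups)
  y <- unlist(groups, use.names = FALSE)
  if (var(y) == 0) stop("degenerate input: all values tied")
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- kruskal.test(y, g)
  pw <- .pairGrid(names(groups))
  if (pairwise == "dunn") {
    r <- rank(y)
    N <- length(y)
    rmeans <- tapply(r, g, mean)
    ns <- lengths(groups)
    ties <- table(y)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    sigma2 <- N * (N + 1) / 12 - tieCorr
    est <- rmeans[pw$group1] - rmeans[pw$group2]
    se <- sqrt(sigma2 * (1 / ns[pw$group1] + 1 / ns[pw$group2]))
    z <- est / se
    pw$estimate <- unname(est)
    pw$statistic <- unname(z)
    pw$p <- unname(2 * pnorm(-abs(z)))
  } else {
    res <- mapply(function(a, b) {
      w <- suppressWarnings(wilcox.test(groups[[a]], groups[[b]],
                                        exact = FALSE, correct = FALSE))
      c(w$statistic, w$p.value)
    }, pw$group1, pw$group2)
    pw$estimate <- NA_real_
    pw$statistic <- res[1, ]
    pw$p <- res[2, ]
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw)
}

#' Dunnett many-to-one comparisons with Monte Carlo adjustment
#'
#' Compares every treatment group against the control using the pooled-MSE t
#' statistics, adjusting familywise by the Monte Carlo null distribution of
#' the maximum absolute statistic over the correlated family (treatments
#' share the control mean and the variance estimate).
#'
#' @param groups Named list of numeric vectors.
#' @param control Name of the control group.
#' @param nMC Monte Carlo draws for the null max-|t| distribution
#'   (default 1e5).
#' @param seed Integer seed for the Monte Carlo draw.
#' @return `data.frame` with one row per treatment: `group`, `estimate`,
#'   `statistic`, `p` (familywise-adjusted, two-sided).
#' @export
dunnettVsControl <- function(groups, control, nMC = 1e5, seed = 1L) {
  groups <- .checkGroups(groups)
  if (!control %in% names(groups))
    stop(sprintf("control group '%s' not found", control))
  fit <- anovaOneway(groups)
  trt <- setdiff(names(groups), control)
  est <- fit$means[trt] - fit$means[[control]]
  se <- sqrt(fit$MSE * (1 / fit$ns[trt] + 1 / fit$ns[[control]]))
  tstat <- est / se
  maxT <- .dunnettNullMax(fit$ns[trt], fit$ns[[control]], fit$df2, nMC, seed)
  p <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
  data.frame(group = trt, estimate = unname(est),
             statistic = unname(tstat), p = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Null of (T_1..T_m): T_i = (U_i/sqrt(n_i) - U_0/sqrt(n_0)) /
## (S * sqrt(1/n_i + 1/n_0)), U ~ N(0,1) iid, S^2 ~ chi^2_df / df.
.dunnettNullMax <- function(nTrt, nCtl, df, nMC, seed) {
  set.seed(seed)
  m <- length(nTrt)
  u0 <- rnorm(nMC)
  s <- sqrt(stats::rchisq(nMC, df) / df)
  maxT <- rep(0, nMC)
  for (i in seq_len(m)) {
    ti <- (rnorm(nMC) / sqrt(nTrt[i]) - u0 / sqrt(nCtl)) /
      (s * sqrt(1 / nTrt[i] + 1 / nCtl))
    maxT <- pmax(maxT, abs(ti))
  }
  maxT
}

#' Spearman rank correlation
#'
#' Mid-rank handling of ties, asymptotic two-sided p; pairs with a missing
#' member are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p`, `n`.
#' @export
spearmanCor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample independent t test
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param welch Use the Welch unequal-variance form instead of the pooled
#'   default.
#' @return List with `t`, `df`, `p` (two-sided), `estimate` (mean
#'   difference).
#' @export
twoSampleT <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       estimate = mean(x) - mean(y))
}

.pLabel <- function(p, alpha, trend) {
  ifelse(p < alpha, "significant", ifelse(p < trend, "trend", "ns"))
}

#' Run the full group-comparison decision tree
#'
#' Shapiro-Wilk normality is tested within every group at the 0.05 level. If
#' all groups pass, a one-way ANOVA is run: an ANOVA p below the trend
#' threshold (significant or trending) is followed by Fisher LSD pairwise
#' tests, otherwise by Tukey HSD. If any group fails normality, the
#' comparison is rerun nonparametrically: Kruskal-Wallis with Dunn pairwise
#' follow-up. Every pairwise p is labelled `significant` (p < `alpha`),
#' `trend` (`alpha` <= p < `trend`), or `ns`. The fired rules are recorded
#' in order.
#'
#' @param groups Named list of numeric vectors, each of length >= 3.
#' @param alpha Significance threshold (default 0.05).
#' @param trend Trend threshold (default 0.1; must exceed `alpha`).
#' @param pairwiseNonparam Passed to [kruskalWallisPairwise()].
#' @return A [GroupComparisonResult-class].
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 2))
#' res <- compareGroups(g)
#' decisionPath(res)
#' pairwiseResults(res)
#' @export
compareGroups <- function(groups, alpha = 0.05, trend = 0.1,
                          pairwiseNonparam = c("dunn", "ranksum")) {
  pairwiseNonparam <- match.arg(pairwiseNonparam)
  groups <- .checkGroups(groups)
  if (all(vapply(groups, var, numeric(1)) == 0) &&
      var(unlist(groups)) == 0)
    stop("degenerate input: zero variance in every group")
  path <- character()
  norm <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    if (var(v) == 0)
      return(data.frame(group = nm, W = NA_real_, p = 0))
    sw <- shapiro.test(v)
    data.frame(group = nm, W = unname(sw$statistic), p = sw$p.value)
  }))
  allNormal <- all(norm$p >= 0.05)
  path <- c(path, sprintf("Shapiro-Wilk per group at alpha=0.05: %s",
                          if (allNormal) "all groups pass -> one-way ANOVA"
                          else "normality rejected -> Kruskal-Wallis"))
  if (allNormal) {
    fit <- anovaOneway(groups)
    omnibus <- list(test = "anova", statistic = fit$F,
                    df = c(fit$df1, fit$df2), p = fit$p, MSE = fit$MSE,
                    df_resid = fit$df2)
    if (fit$p < trend) {
      path <- c(path, sprintf(
        "ANOVA p=%.4g < %.2g (significant or trend) -> Fisher LSD post hoc",
        fit$p, trend))
      posthoc <- "fisher_lsd"
      pw <- fisherLSD(fit)
    } else {
      path <- c(path, sprintf(
        "ANOVA p=%.4g >= %.2g -> Tukey HSD post hoc", fit$p, trend))
      posthoc <- "tukey_hsd"
      pw <- tukeyPairwise(fit)
    }
  } else {
    kw <- kruskalWallisPairwise(groups, pairwiseNonparam)
    omnibus <- list(test = "kruskal_wallis", statistic = kw$H, df = kw$df,
                    p = kw$p)
    posthoc <- paste0("kw_", pairwiseNonparam)
    path <- c(path, sprintf(
      "Kruskal-Wallis H=%.4g, p=%.4g -> %s pairwise follow-up",
      kw$H, kw$p, pairwiseNonparam))
    pw <- kw$pairwise
  }
  pw$label <- .pLabel(pw$p, alpha, trend)
  new("GroupComparisonResult", normality = norm, omnibus = omnibus,
      posthoc = posthoc, pairwise = pw, path = path, alpha = alpha,
      trend = trend)
}
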