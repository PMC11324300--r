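# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# One-way ANOVA by explicit sum-of-squares decomposition.
oracleAnova <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  k <- length(groups)
  N <- length(y)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE), MSE = ssw / df2,
       df1 = df1, df2 = df2)
}

# Pairwise pooled-error t test (Fisher LSD) from the raw data.
oracleLSD <- function(groups, i, j) {
  o <- oracleAnova(groups)
  est <- mean(groups[[i]]) - mean(groups[[j]])
  se <- sqrt(o$MSE * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
  t <- est / se
  list(t = t, p = 2 * pt(-abs(t), o$df2))
}

# Kruskal-Wallis H with tie correction, from the rank definition.
oracleKW <- function(groups) {
  y <- unlist(groups)
  r <- rank(y)
  N <- length(y)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), numeric(1))) -
    3 * (N + 1)
  ties <- table(y)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  df <- length(groups) - 1
  list(H = H, p = pchisq(H, df, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up from its definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive recount of a staged cohort's stage/pattern table.
oracleRecount <- function(stagePerAnimal, patternPerAnimal) {
  keep <- !is.na(stagePerAnimal)
  st <- stagePerAnimal[keep]; pt <- patternPerAnimal[keep]
  n <- length(st)
  counts <- c(table(factor(st, c("NonS", "PS", "S"))),
              table(factor(pt, c("none", "G", "M", "T", "GM", "GT",
                                 "MT", "GMT"))))
  list(n = n, counts = counts, pct = round(100 * counts / n, 1))
}

nullGroups <- function(k = 4, n = 10, mu = rep(0, k)) {
  setNames(lapply(seq_len(k), function(i) rnorm(n, mu[i])),
           paste0("g", seq_len(k)))
}
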