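---
title: "Staging sarcopenia in mice: model, parameters, and design choices"
author: "sarcomice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging sarcopenia in mice: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomice)
```

# The staging model

Sarcopenia — the age-related loss of skeletal muscle mass and function — is
diagnosed in people by consensus criteria (EWGSOP2) that lead with muscle
strength and confirm with muscle quantity and physical performance. This
package transfers that logic to aged C57BL/6J mice using three terminal or
behavioural measurements:

* **G** — forelimb grip strength (g), the strength criterion;
* **M** — total hindlimb muscle mass (mg), the quantity criterion;
* **T** — treadmill time to exhaustion (s), the performance criterion.

For each sex, a *young reference* cohort defines the norm: for measurement
$m$ the cutoff is

$$c_m = \bar{x}_m^{\text{young}} - 2\, s_m^{\text{young}},$$

the mean minus two sample standard deviations ($n-1$ denominator) of young
animals of the same sex. An old animal *fails* a criterion when its
measurement is **strictly below** the cutoff; a value exactly at the cutoff
passes. Counting failed criteria stages the animal:

| deficits | stage |
|---|---|
| 0 | NonS (non-sarcopenic) |
| 1 | PS (probable sarcopenia) |
| 2–3 | S (sarcopenic) |

The combination of failed criteria is kept as a *pattern label* (letters in
fixed order G, M, T: `G`, `GM`, `GMT`, …), and prevalence is tabulated by
age bracket and pooled, as counts and percentages to one decimal.

```{r staging-example}
cuts <- fixedCutoffs("male", grip = 131, mass = 708, treadmill = 514)
cohort <- patternFixtureCohort(
  c(none = 259, G = 303, M = 42, T = 47, GM = 143, GT = 36, GMT = 170),
  cuts)
staged <- stageCohort(cohort, cuts)
prevalenceTable(staged, "pooled")[, c("n", "NonS_pct", "PS_pct", "S_pct")]
```

## Missing treadmill data

Treadmill testing is the criterion most often unavailable (animals that
cannot run, equipment limits). Two policies are provided:

* `available` (default): an animal is staged on the criteria that were
  evaluated; a missing criterion is never counted as a deficit. This
  mirrors study designs whose treadmill sample sizes are smaller than their
  grip/mass sample sizes yet stage every animal.
* `complete`: animals missing any criterion are left unstaged (`NA`) and
  reported separately in the prevalence table (`n_unstaged`). This is the
  conservative complete-case reading.

Both are exact on complete data; they differ only in how incomplete animals
enter denominators. Because the question of how such animals were handled
historically is not settled, the choice is an explicit parameter rather
than a hidden default.

## Rounding

Published cutoffs are integers. `deriveCutoff(..., rounding = "integer")`
reproduces that reporting convention, while classification defaults to the
unrounded cutoff to avoid a hidden bias of up to half a unit; passing the
rounded set to `stageCohort()` replicates published tables exactly.

# The reference model's parameters

* **Young window**: ages treated as "young", default 4–9 months for males
  and 6–7 months for females (closed intervals, months). A sensitivity
  window of 4–6 months can be passed to `computeReference()` /
  `deriveCutoffs()`.
* **Old brackets**: half-open intervals labelling old animals, default
  23–24, 25–26, 27–28, 29–30, >30 months for males and a single 27–28
  bracket for females. Animals younger than the first bracket are labelled
  `young`; an age in a gap is a configuration error rather than a silent
  drop.
* Normalized phenotypes — grip/body-weight (g/g), grip/hindlimb-mass
  (g/mg), percent-of-young scaling, and specific force (peak tetanic force
  over physiological cross-sectional area, mN/mm²) — are provided as plain
  transformations with unit bookkeeping.

# The statistical decision tree

Group comparisons (e.g., grip strength across NonS/PS/S, or across age
brackets) follow a fixed, fully recorded decision path:

1. **Shapiro–Wilk** within every group at $\alpha = 0.05$. The gate is
   *all-groups*: a single failing group routes the whole comparison to the
   nonparametric branch. This is the strictest reading of "normality within
   each group"; the per-group $\alpha$ is a documented constant, not an
   option, so that decision paths are comparable across datasets.
2. All groups normal → **one-way ANOVA**. ANOVA $p < 0.1$ (significant or
   trending) → **Fisher LSD** pairwise tests (unadjusted, pooled error);
   ANOVA $p \ge 0.1$ → **Tukey HSD** (studentized range, Tukey–Kramer for
   unequal $n$).
3. Any group non-normal → **Kruskal–Wallis** (tie-corrected) with **Dunn**
   pairwise follow-up on the pooled mid-ranks, unadjusted — mirroring the
   LSD spirit; Wilcoxon rank-sum follow-up is available as an option.
4. Every pairwise $p$ is labelled `significant` ($p<0.05$), `trend`
   ($0.05 \le p < 0.1$) or `ns`, with the exact $p$ always reported.

`compareGroups()` returns the whole path (`decisionPath()`), so a result
can be audited without rerunning it.

**Dunnett many-to-one comparisons** (treatments vs a control, as used for
force–frequency curves) adjust familywise via the Monte Carlo null of the
maximum absolute statistic over the correlated family — treatments share
the control mean and the pooled variance estimate, so the statistics are
drawn jointly as
$T_i = (U_i/\sqrt{n_i} - U_0/\sqrt{n_0}) / (S\sqrt{1/n_i + 1/n_0})$ with
$S^2 \sim \chi^2_\nu/\nu$. The default $10^5$ draws give adjusted $p$
accurate to about $\pm 0.002$ near 0.05 and are seed-reproducible; the
Monte Carlo route was chosen over multivariate-$t$ quadrature for
transparency and because its error is negligible at reporting precision
(it agrees with `multcomp`'s quadrature to $<0.005$ in the test suite).

# The synthetic cohort generator

Real phenotype data for this design are not freely redistributable, so the
package carries a generator that emulates the statistical structure the
analysis assumes; every downstream stage is exercised against it.

* **Marginals** are normal per measurement per group. Published summaries
  report group means (and declines) only, so normality is the simplest
  model consistent with the mean − 2 SD cutoff logic.
* **Young references** default to grip 165 ± 17 g, mass 850 ± 71 mg,
  treadmill 750 ± 118 s (males) and 160 ± 17 g, 745 ± 62 mg, 800 ± 112 s
  (females). These are *free parameters chosen so that mean − 2 SD lands on
  the published integer cutoffs* (131/708/514 and 126/621/576); they are
  not published values themselves, and checks that "recover" the cutoffs
  from simulated animals are parameter-recovery checks, not reproductions
  of the original data.
* **Bracket declines** (percent of young, by mean): males 21/15/20 at
  23–24 months and 34/30/51 beyond 30 months for grip/mass/treadmill, the
  published endpoints, with intermediate brackets interpolated linearly;
  females 13/13/13 at 27–28 months. Old within-bracket SDs are exposed as
  configuration and default to the young SDs, since old-group variances are
  not published.
* **Dependence** is a Gaussian copula: the target Spearman matrix (default
  grip↔mass 0.48, other pairs 0.30 — "moderate positive") is mapped
  elementwise to the latent Pearson scale by $2\sin(\pi\rho_s/6)$, which is
  exact for normal margins; a non-positive-definite latent matrix is a
  configuration error naming the offending entries. This calibration is
  exact and fast, avoiding rejection sampling.
* **Missingness**: treadmill values are deleted completely at random with
  probability 0.19 by default (the fraction implied by typical
  treadmill-vs-grip sample-size gaps).
* **Floor**: physical measurements are positive, so draws below 0.1
  measurement units are truncated there and the truncation rate is
  reported as a warning. Under realistic settings the rate is zero.

What the generator does **not** emulate: longitudinal trajectories and
attrition, age as a continuous covariate within brackets (declines are
bracket-constant), non-normal tails, informative missingness, and
body-composition dynamics (body weight is an independent nuisance column).
Passing tests therefore demonstrate correctness of the pipeline's logic and
calibration of its tests under the stated model — not robustness to every
feature of real colony data.

# The proteomics screen

The screen reconstructs a mechanism: which protein sets co-vary with the
sarcopenia measurements consistently in young and old animals.

1. **Per-protein association**: within each age cohort, ordinary
   least-squares of abundance on the trait; the per-protein summary is the
   $t$ statistic, making the screen invariant to per-protein abundance
   scale. Perfect fits are capped at $|t| = 10^8$; missing abundances are
   dropped pairwise.
2. **Competitive set test**: two-sided Wilcoxon rank-sum of in-set vs
   out-of-set $t$ statistics; direction is the sign of the median
   difference. The null model treats proteins as exchangeable — inter-protein
   correlation is *not* modelled (no camera-style variance inflation), and
   the synthetic generator's background matches that null by construction;
   on real proteomes correlated sets will be anticonservative.
3. **Main effect**: sets whose direction agrees in both cohorts get a
   combined $p$ by Stouffer's method (equal weights, directional $z$ from
   each two-sided $p$); discordant sets are excluded from candidacy.
   Benjamini–Hochberg $q$ values are computed across the combined $p$ of
   candidate sets and flagged at $q < 0.05$. The top five contributors per
   set are the members with the largest $|t|$ averaged over cohorts.

Because the original study's exact competitive test and combination rule
live in supplementary methods, this module is a documented reconstruction;
its validation is mechanism-level (null uniformity, FDR behaviour,
injected-signal recovery), not a reproduction of any specific pathway
table. The synthetic proteomics generator injects
`abundance = strength × standardized trait + noise`, so an injected
strength $s$ with unit noise yields a per-protein correlation of
$s/\sqrt{s^2+1}$.

# Numerical and design notes

* Sample SDs use the $n-1$ denominator throughout.
* Gene-set identifiers are matched to matrix row ids exactly
  (case-sensitive); unmatched members are dropped and counted.
* `bhFDR()` delegates to the standard step-up implementation and is tested
  against a brute-force implementation of the definition.
* Degenerate inputs error early and descriptively: all-tied groups, groups
  under three values, constant traits, sets covering the whole universe,
  fewer than two reference animals.
* The command-line surface (`simulate`, `classify`, `prevalence`,
  `compare`, `genesets`, installed as `exec/sarcomice`) is a thin wrapper
  over the exported functions; each run writes a `.log` with the tool
  version, configuration and seeds sufficient to reproduce its outputs.

## Problem sizes used in the checks

Validation simulations use sizes chosen to bound Monte Carlo error well
below the tolerances being asserted: 2000 animals per group for marginal
(±2%) and missingness (±0.02) fidelity, 5000 for rank-correlation fidelity
(±0.05), 50 000 young animals for integer-level cutoff recovery, 2000 null
replicates for the 0.035–0.065 calibration band of ANOVA / Kruskal–Wallis /
Dunnett at $\alpha = 0.05$, 1000 random sets for competitive-test
uniformity, and 100 seeds for the ≥80% injected-set recovery check
(strength 0.6, set size 30, 40 samples per cohort).

# Known limitations

* Cutoffs are normative (mean − 2 SD), not percentile- or regression-based;
  with a zero-SD reference the cutoff degenerates to the mean.
* Stages collapse the human "severe sarcopenia" tier into the 2–3 deficit
  count; no severity sub-grading.
* The decision tree applies its normality gate per comparison; it does not
  pool normality evidence across related panels.
* The competitive test's exchangeable null understates variance for
  strongly co-regulated sets (see above).
* The generator draws ages uniformly within brackets and treats the
  bracket, not age, as the unit of decline.
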