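---
title: "Judgment-variable extraction and anxiety-level prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judgment-variable extraction and anxiety-level prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rptanx implements a complete analysis chain from a short picture rating
task and a survey to the prediction of state anxiety levels. This
vignette is the package's account of the underlying models, the numerical
conventions it adopts, the design choices that were genuinely open, and
what its synthetic cohorts do and do not tell you about real data.

## The rating task and the relative preference representation

Participants rate 48 pictures (6 categories x 8 pictures) on an integer
scale from -3 (dislike very much) to +3 (like very much), 0 being
neutral. For each participant and category the ratings are split by sign
— zeros belong to neither set — and each signed set is summarised by a
triple $(K, \sigma, H)$:

* $K$ — the mean rating of the set (value; $K^+ \in (0,3]$,
  $K^- \in [-3,0)$),
* $\sigma$ — the variance of the set (risk),
* $H$ — the Shannon entropy, in bits, of the empirical distribution of
  rating magnitudes $\{1,2,3\}$ within the set (information,
  $0 \le H \le \log_2 3$), with $0\log 0 := 0$.

Three curve families are then fit per participant by ordinary least
squares:

* **Value function** (per limb): $K = a\ln H + b$ and $K = bH^{a}$ are
  both fit to the six per-category $(H, K)$ points of each sign; the
  family with the higher adjusted $R^2$ on the original scale is
  retained (ties go to the logarithm). Points with $H = 0$ are excluded
  (undefined logarithm) and recorded in the diagnostics. The positive
  limb is expected to rise ($a^+ > 0$) and the negative limb to fall.
* **Limit function**: a single concave quadratic
  $\sigma = \alpha K^2 + \beta K + \gamma$ across the twelve signed
  $(K, \sigma)$ points. Concavity ($\alpha < 0$) and real roots
  $r^- < 0 < r^+$ are required for the derived features.
* **Tradeoff function**: each category's $(H^+, H^-)$ pair is mapped to
  polar coordinates $r = \sqrt{(H^+)^2 + (H^-)^2}$,
  $\theta = \operatorname{atan2}(H^-, H^+)$, and the radial distribution
  is summarised.

From these, 15 judgment variables are extracted:

| Feature | Definition here |
|---|---|
| LA (loss aversion) | $|a^-|/a^+$, slopes evaluated at $H = 1$ |
| RA (risk aversion) | $|f''_+(\bar H^+)|$, curvature of the positive limb at the participant's mean positive entropy |
| LR (loss resilience) | $|f''_-(\bar H^-)|$, the same in the domain of losses |
| Ante | value of the positive limb at unit entropy ($b^+$ for the log family) |
| Insurance | magnitude of the negative limb at unit entropy |
| Reward TP / Aversion TP | roots $r^+$ and $|r^-|$ of the limit quadratic |
| Peak PR / Peak NR | maximum fitted $\sigma$ over $(0, r^+]$ resp. $[r^-, 0)$; when the vertex falls outside the half-interval, the supremum is taken at the open endpoint, evaluated at $K = 0$ |
| Total RR / Total AR | $\int_0^{r^+} \sigma(K)\,dK$ and $|\int_{r^-}^0 \sigma(K)\,dK|$, closed-form antiderivatives |
| RA tradeoff / Tradeoff range | mean and range of $\theta$ |
| RA consistency / Consistency range | mean and range of $r$ |

Curvatures are taken from the retained family's second derivative:
$-a/H^2$ for the logarithm, $ba(a-1)H^{a-2}$ for the power law. The
operationalizations of Ante and Insurance as the limb values at unit
entropy follow their descriptions (the stake one would pay to enter a
game of chance; the security one would acquire against losses); each
formula is a single small function, so a different convention can be
substituted without touching the rest of the chain.

Fit failures never raise errors: a limb with fewer than three usable
points, a convex limit fit, or roots of the same sign simply leave the
affected features undefined and mark the profile incomplete.

## Survey scoring and exclusion rules

The 20 state-anxiety items are answered on a 4-point Likert scale and
summed after reverse-keying items {1, 2, 5, 8, 10, 11, 15, 16, 19, 20}
($r \mapsto 5 - r$), giving a score in $[20, 80]$. The reverse key is a
configurable argument. Invalid records (missing or out-of-range items)
are rejected, never imputed.

Participants are excluded when they (1) straight-line any declared
question section (zero response variance), (2) report ten or more of 17
clinician-diagnosed illnesses, (3) report an education level inconsistent
with their years of education (an editable consistency table), or (4)
complete the survey in under 800 s. Rating-based exclusions remove
participants whose 48 ratings span at most one point, whose judgment
profile is incomplete, or who are extreme outliers — beyond 5 MAD of the
cohort median on any feature (the multiplier is configurable; "extreme"
is not otherwise quantified in the source material). All rules are
evaluated independently, so their order cannot change the retained set.

Age is additionally binned to three levels for the group tests; the
18–39 boundary separates younger adults and the upper cut (default 55)
is configurable, since only the first boundary is anchored.

## Classification

Anxiety scores are thresholded at 35, 45 and 55 (roughly the 50th, 75th
and 90th percentiles); scores at or above the threshold are 'higher',
the positive class. Data are split 70:30 by simple random sampling
(stratification is available behind a flag), and forests of 1000 trees
with 5 candidate variables per split are grown on the 26 predictors (15
judgment + 11 contextual).

The balanced variant (bRF) draws, for every tree's bootstrap, an equal
number of samples from each class — the minority-class size — so the
majority class is down-sampled during training only. Out-of-bag accuracy
and all test metrics are computed on untouched, imbalanced data.
Sensitivity, specificity, accuracy and balanced accuracy are reported in
percent; the AUC is computed from continuous out-of-class vote fractions
(hard labels would give a degenerate ROC). A permutation null — labels
shuffled, the full train/evaluate procedure repeated, metrics averaged
over 100 iterations — calibrates chance performance.

Feature importance is the mean decrease in Gini, normalized by its sum so
shares sum to one, with group sums for the four headline contextual
variables (age, loneliness, income, employment), the 15 judgment
variables, and the rest. Proximities count the fraction of trees in
which two samples share a terminal node; classical metric MDS on
$1 - P$ gives the 2-D cluster view.

## Mediation and moderation

For a judgment variable $X$, a contextual variable $Me$ and anxiety
score $Y$, three regressions are fit:
$Y = \gamma_1 + cX$, $Me = \gamma_2 + aX$,
$Y = \gamma_3 + c'X + b\,Me$. The Sobel statistic is
$z = ab/\sqrt{b^2 s_a^2 + a^2 s_b^2}$ (identically
$(c - c')/\sqrt{\cdot}$, since $c - c' = ab$ holds exactly for nested
OLS), with a two-tailed normal p-value, and the mediated percentage is
$T_{\mathrm{eff}} = 100\,(1 - c'/c)$. Mediation is significant when
$p_a, p_b, p_c < 0.05$, $p_{\mathrm{Sobel}} < 0.05$ and
$T_{\mathrm{eff}} > 50$. A secondary run swaps $X$ and $Me$; mediation
is "directed" when the original is significant and the swap is not.

Moderation fits $Y = \beta_0 + \beta_1 X + \beta_2 Mo + \beta_3 X Mo$
against the restricted model without the interaction; $\beta_3$ is
tested by a partial F-test (equal to the squared-t test for one added
regressor) and the full model by an overall F-test, both required at
0.05.

Ordinal contextual variables enter these regressions as numeric codes,
mirroring the single-coefficient treatment; a categorical-dummy encoding
is available behind a flag. The 4 x 15 screens are reported at raw
significance — no multiple-testing correction by default, with a
Bonferroni option — because the screens are descriptive posterior
analyses of the classifier's top predictors, not confirmatory tests.

## Post hoc group differences

Anxiety scores are compared across the levels of ten contextual
variables with the Wilcoxon rank-sum test (two levels) or the
tie-corrected Kruskal–Wallis test (more than two). Each judgment
variable is compared between higher and lower anxiety groups at each
threshold with both one-sided Wilcoxon tests; Bonferroni correction is
applied within each variable across its six tests
($\alpha = 0.05/6 \approx 0.0083$). The normal approximation with tie
correction is used at cohort scale, the exact distribution when both
groups are under 50.

## The synthetic cohort generator

Every downstream stage is tested against cohorts from
`generate_cohort()`, which emulates the statistical structure the
analysis assumes.

A latent trait $z \sim N(0,1)$ drives everything, scaled by
`anxiety_effect` (default 1.5). STAI items follow a cumulative-logit
model with shared thresholds chosen so the scored sum centres in the
high 30s; the item slope was calibrated so that at the default effect a
cohort of 2000 gives a Spearman correlation above 0.5 between $z$ and
the scored sum (it lands near 0.95). Contextual variables shift along
declared monotone directions — loneliness, female sex and COVID-19
history upward; age, income and education downward — with marital
status, employment and race left unlinked by default.

Ratings are generated per category from distributions over the magnitude
grid $\{1,2,3\}$. Rather than sampling from truncated normals, each
category's distribution is the unique three-atom distribution with a
target mean and variance; targets move along a path on which mean and
entropy rise together within each sign (giving the expected positive
value-limb slope) while variance falls with $|K|$ across the signed axis
(giving a concave limit curve). This resolves a real tension of the
3-point magnitude grid: entropy and variance are strongly coupled, so
arbitrary target combinations are infeasible. Sets are drawn as
quasi-exact compositions (largest-remainder rounding of expected counts,
plus a one-unit stochastic move) because fully multinomial draws of 3–5
ratings make the realized $(K,\sigma,H)$ so noisy that limb slopes
attenuate several-fold and the limit fit's concavity flips for most
participants — the generator could not then exhibit the structure the
analysis is meant to recover.

Three trait-linked mechanisms plant the declared judgment-variable
shifts for the high-anxiety stratum:

1. the positive-limb window widens with $z$, flattening $a^+$ (raising
   LA and lowering RA);
2. the negative-limb variance floor rises with $z$, compressing the
   negative entropy range and steepening $a^-$ (raising LA);
3. two "decisive aversion" categories — all pictures of the aversive
   categories rated −3 — occur with a probability that falls with $z$.
   Their zero-entropy tuples stay out of the value-limb fits, extend the
   limit curve's tent, lower the low-anxiety stratum's mean negative
   entropy (raising its LR), and anchor a zero tradeoff angle (widening
   its tradeoff range). The net effect is lower LR and a narrower
   tradeoff range in the high-anxiety stratum.

Lever strengths (defaults `la = 0.15`, `lr = 0.40`, `tradeoff = 2.6`)
were calibrated once against the generator's contract — the planted
directions must be recoverable by the one-sided rank-sum tests on
cohorts of 2000 — and verified across independent seeds.

What the generator does **not** emulate: the semantic content of the
stimuli; exact census margins (categorical frequencies are plausible
approximations); within-category rating overdispersion (compositions are
deliberately under-dispersed relative to multinomial sampling); and the
real study's exclusion rate — about 28% of generated profiles are
incomplete (concavity or slope-sign failures under sampling noise),
against roughly 13.5% excluded in comparable real cohorts. Passing tests
therefore demonstrate that the pipeline recovers structure that is
present, not that real rating data have this structure.

## Numerical conventions and degenerate inputs

* Entropy in bits; population variance for $\sigma$ (the sets are small
  and of fixed size); both conventions are config flags.
* Value limbs are fit as $K = f(H)$; an axis-swap flag exists because
  the orientation of the published curve plots is ambiguous. The limit
  quadratic is fit jointly across both signs (a per-limb flag exists).
* Family selection by adjusted $R^2$; ties go to the logarithm.
* Peak risks at a vertex outside the half-interval evaluate the open
  endpoint at $K = 0$ — the "peak risk that must be overcome" reading of
  a maximum over the approach/avoidance domain.
* Outlier rule: $|x - \mathrm{med}| > 5 \cdot \mathrm{MAD}$ (standard
  consistency constant), configurable.
* Degenerate inputs (empty signed sets, $H = 0$ points, convex limit
  fits, same-sign roots, constant moderators, aliased mediators) are
  either flagged-and-excluded or raised as errors at the statistical
  modules' boundaries, as documented per function; curve-fit failures
  never raise.
* Loneliness is generated and encoded with 5 ordinal levels by default
  (the response scale's exact cardinality is survey-specific and
  exposed as a parameter).

## Problem sizes

The test suite and the acceptance script run on synthetic cohorts of
2000 participants for direction-recovery and correlation checks, 500-row
subsets with 100 iterations for the permutation null, 1000 observations
for the mediation chain oracle, 500 simulations for the moderation
type-I rate, and 100 seeded runs for the Gini ranking check. These sizes
were chosen so each check's statistical resolution comfortably exceeds
the effect it verifies.

## Known limitations

* The 3-point magnitude grid tightly couples $K$, $\sigma$ and $H$;
  participants whose sampled sets land in unfavourable corners lose
  their profile, and this exclusion is mildly correlated with the trait
  (completeness is a few points lower in the high-anxiety stratum).
* LA is a ratio of two fitted slopes and is the noisiest planted
  feature; its recovery is reliable at cohorts of 2000 but not at a few
  hundred.
* The mediation verdict follows the classical causal-steps-plus-Sobel
  rule; bootstrap confidence intervals and modern indirect-effect
  estimators are out of scope.
* The deposited participant table of the original study is not
  distributed with the package; the ingestion path
  (`read_participant_table()`) and the reproduction benchmarks are in
  place for users who obtain it.
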