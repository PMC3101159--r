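---
title: "Adaptive measurement with the rating-scale Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive measurement with the rating-scale Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschcat)
```

## The measurement model

raschcat measures a single latent trait — the motivating application is
hospital employees' job satisfaction on a four-point agreement scale — with
the rating-scale Rasch model. Person $n$ has a measure $\theta_n$ in logits,
item $i$ a difficulty $\delta_i$, and all items share one vector of step
calibrations $\tau_1, \dots, \tau_M$ for the $M+1$ ordered categories coded
$0 \dots M$. The probability of category $k$ is

$$P(X_{ni} = k) \;=\;
\frac{\exp\!\sum_{j=1}^{k}(\theta_n - \delta_i - \tau_j)}
     {\sum_{h=0}^{M}\exp\!\sum_{j=1}^{h}(\theta_n - \delta_i - \tau_j)},$$

with the empty sum equal to zero. Equivalently, adjacent categories obey
$P_k/(P_k + P_{k-1}) = \mathrm{logistic}(\theta - \delta - \tau_k)$: the
step calibration $\tau_k$ is the point (relative to the item) where
categories $k-1$ and $k$ are equally likely. The shared-threshold
restriction is what distinguishes this family from the partial-credit
model; partial credit, graded-response and two-parameter models are
deliberately out of scope.

Three derived functions drive everything else: the expected score
$E = \sum_k k P_k$, the category-score variance
$W = \sum_k k^2 P_k - E^2$ (which equals the Fisher information of the item
about $\theta$), and the log-likelihood of a response pattern. Exponent
ladders are always centred on their maximum before exponentiation, so
probabilities remain finite for any finite logits.

Survey-facing files store the familiar 1–4 ratings; internally categories
are 0–3 so that the step index $j = 1 \dots M$ lines up with the model's
sum. Every file header states which coding it uses.

## Person estimation

`estimate_theta()` maximises the response-pattern likelihood by
Newton–Raphson:
$\theta \leftarrow \theta + (\sum_i x_i - \sum_i E_i)/\sum_i W_i$.
Defaults: tolerance 0.001 logits on the update, at most 50 iterations, each
step capped at 1 logit, $\theta$ clamped to $[-10, 10]$. The caps guard
against overshooting on short, extreme-ish patterns; the clamp bounds the
scale at a range far beyond any interpretable measure. Raw scores of all-0
or all-$M$ have no finite maximiser, so they are moved 0.25 score units
toward the interior — a long-standing Rasch reporting convention — and the
estimate is flagged `extreme`. The reported standard error is
$1/\sqrt{\sum_i W_i(\hat\theta)}$.

The test suite cross-checks the estimator against a brute-force grid search
of the log-likelihood on $[-10, 10]$ at step 0.001, on hundreds of random
patterns, demanding agreement within 0.005 logits.

## Joint calibration

`jmle_calibrate()` estimates person measures, item difficulties and the
shared thresholds by alternating damped Newton–Raphson updates (joint
maximum likelihood). Two choices deserve explanation.

**Identification.** The likelihood is invariant to two location
trade-offs: persons against items, and items against thresholds (and hence,
with items fixed, persons against thresholds). Unanchored runs therefore
impose mean difficulty 0 and thresholds summing to 0, by projecting each
Newton step onto the constraint. When an anchor bank fixes the
difficulties, the person/threshold trade-off is *still* free — anchoring
difficulties does not pin the threshold location — so anchored runs inherit
the threshold sum from the anchor scale and estimate only the spacing.
Projecting steps (rather than re-centring parameters after the fact) keeps
the constraints exact at every iteration and avoids a neutral limit cycle
between the person and threshold blocks that plain re-centring produces.

**Person updates.** Inside the calibration loop, person measures are
updated with Warm's weighted-likelihood score,
$r_n - \sum_i E_{ni} + \sum_i \mu_{3,ni} / (2\sum_i W_{ni})$, where
$\mu_3$ is the third central category moment. The plain MLE is biased
outward and undefined at extreme scores; with a finite bank both effects
propagate into the thresholds, inflating the recovered spacing noticeably
at the rarely-used extreme categories. The weighted-likelihood score
removes the first-order bias and is finite at extreme raw scores, so every
respondent informs the thresholds. Reported person measures are still the
conventional (interiorised) MLE from `estimate_persons()`, for consistency
with the adaptive-testing engine.

Items whose observed responses never vary are inestimable and are dropped
with a warning. Missing cells are simply omitted from all sums. Convergence
is declared when the largest parameter update falls below `tol`
(default $10^{-4}$ logits); the result is deterministic in its inputs.

## Fit, reliability, and the stopping value

Standardized residuals $z_{ni} = (x_{ni} - E_{ni})/\sqrt{W_{ni}}$ yield the
two mean-square fit statistics: outfit (plain mean of $z^2$,
outlier-sensitive) and infit ($\sum(x-E)^2/\sum W$, information-weighted),
both with expectation 1 under the model. Standardized $Z$ values use the
Wilson–Hilferty cube-root transform with the model variance of the
mean-square. The misfit screen discards items with infit outside
$[0.5, 1.5]$ (closed interval, single pass — no purify-and-refit, which the
workflow does not call for).

Person-separation reliability is
$R = (\mathrm{Var}(\hat\theta) - \overline{SE^2}) / \mathrm{Var}(\hat\theta)$,
floored at zero, excluding extreme persons. From a reference calibration
with person SD $SD_x$ it implies the standard error of measurement
$SEM = SD_x\sqrt{1-R}$ — the adaptive test's stopping target: stop once the
provisional measure is as precise as the full-length instrument. With the
packaged bank's reference values ($SD_x = 1.99$, $R = 0.88$) the rule
truncates to 0.68 logits.

## Unidimensionality and category diagnostics

`residual_pca()` eigen-decomposes the item-by-item correlation matrix of
the standardized residuals. Under a single latent dimension the residuals
are near-independent noise: eigenvalues concentrate near 1, up to the
Marchenko–Pastur spread at finite sample sizes and one near-null direction
created by the within-person residual constraint at the fitted measure.
Three conventional criteria are reported and left to the caller's policy:
variance explained by the measures (computed as
$100\,\mathrm{Var}(E)/(\mathrm{Var}(E) + \overline{W})$ over scored cells)
of at least 60%; first contrast eigenvalue below 3; first-contrast variance
below 5%. The first-contrast variance is the eigenvalue as a share of the
*total* (measure plus residual) variance — the convention under which an
eigenvalue of 1.8 on 24 items at ~52% variance explained corresponds to
roughly 4%. Computing it against the residual block alone
(eigenvalue/items) would condemn even perfectly unidimensional data at
realistic sample sizes, since the null largest eigenvalue itself exceeds
5% of the item count.

`category_diagnostics()` checks the four conventional guidelines for a
functioning rating scale: average measures advance monotonically with the
category; step calibrations advance; adjacent steps advance by at least
1.4 logits; and by less than 5.0. Empty categories leave the first
guideline undetermined rather than silently passing.

## The adaptive testing engine

`run_cat()` follows the classic maximum-information loop:

1. The examinee's global self-rating (1–4) maps to a starting measure.
   The default map $(-2.0, -0.5, 0.5, 2.0)$ logits is a design choice —
   monotone, spanning the typical respondent range while staying in the
   information-rich region of the bank — and is config-overridable.
2. The first `burn_in = 3` items are chosen by maximum information at that
   starting measure (the provisional measure does not move during burn-in);
   estimation begins with the fourth response.
3. After each subsequent response the measure is re-estimated from all
   responses so far, and the next item is the unadministered one with
   maximum information at the current measure, ties broken by lowest id.
4. The session stops when at least `min_items = 10` items are answered and
   the SE is at or below the SEM target, or when the bank (or `max_items`)
   is exhausted. An optional aberrance abort (off by default) terminates
   early if the running outfit exceeds a threshold of 10 — kept
   configurable because mid-session aborts leave measures of unknown
   quality; the SE/minimum-length rule is the governing contract.

Each step logs the model probability of the observed response and the
expected score *at the pre-response measure* (what the tester believed
before seeing the answer), then the post-response measure, SE and running
outfit. Responses whose standardized residual exceeds 1.96 in magnitude are
marked `*` in reports as unexpected; a session outfit above 2.0 flags the
record aberrant.

Two numerical facts about session trajectories are worth stating because
they shape the tests. First, the SE sequence declines as information
accumulates, but the logged SE is evaluated at the *moving* estimate, so it
can tick up on the order of 0.001 when a response jumps the measure into a
slightly less informative region; monotone decline is exact at any fixed
evaluation point, and at the two-decimal resolution of the session report.
Second, the session outfit is computed at the measure fitted from the same
$\approx$ 10 responses, which absorbs roughly one degree of freedom: its
expectation under the model is close to $(n-1)/n$, not 1, and the tests
bound it by $1 \pm 2/\text{min\_items}$ while checking that residuals at
the true generating measure average 1.

## Simulation: what it emulates and what it does not

`simulate_cohort()` draws person measures from a normal latent law —
defaults $n = 300$, mean 2.30, SD 1.99 logits, the reference survey's
scale — and generates responses by inverse-CDF sampling of the model's
category distribution. An arbitrary quantile function can replace the
normal law, and per-item difficulty shifts can emulate a follow-up year in
which specific perceptions deteriorated. All randomness flows through R's
seeded generator; a run is fully reproducible from (spec, bank, seed).

Simulated data are *model-true*: they contain no real-world misfit, no
differential item functioning, no local dependence between items, no
response styles, and no demographic structure. Tests passing on such data
certify the estimation and decision machinery — recovery of generating
parameters, nominal error rates, expected fit levels — not the behaviour of
any real instrument. Reliability computed on model-true data is an
upper-bound regime for the same reason.

## Group comparisons

Item-by-item comparisons operate on raw category scores (a logit-scale mode
exists but is off by default): the question "did perceptions on this item
change" is asked on the scale respondents used. The two-group test is
Welch's unequal-variance $t$ with Satterthwaite degrees of freedom. The
choice matters in small unbalanced strata: comparing groups of 6 and 2, the
Satterthwaite df collapses toward the smaller group ($\approx 2$), where
$|t| = 3$ is *not* significant at the 5% level ($p \approx 0.095$) — a
pooled-df test would call it significant. Demographic composition tables
use Pearson's chi-square with Yates continuity correction exactly when the
table is 2×2. No multiple-testing correction is applied across the
item-by-stratum grid; reports state the number of tests performed so the
reader can apply their own policy.

## Problem sizes and numerical defaults

The test and acceptance workloads use the packaged 24-item bank with
cohorts of 300 (survey-sized reliability runs), 800–1000 (fit and
dimensionality properties), and 2000 persons (threshold recovery), with
20–100 seeded replicates for distributional properties — sizes chosen so
the full suite certifies each claim at comfortable statistical margins
while remaining quick to run on one core. Key defaults, all overridable:
NR tolerance 0.001 logits (persons) and $10^{-4}$ (calibration), iteration
caps 50/200, step caps 1.0 logit (0.5 for thresholds), $\theta$ clamp
$[-10, 10]$, extreme-score adjustment 0.25 score units, misfit screen
$[0.5, 1.5]$ on infit, SE target 0.68 for the packaged bank, burn-in 3,
minimum length 10, aberrance outfit 2.0, unexpected-response $|z| > 1.96$.

## Known limitations

- Joint maximum likelihood is inconsistent in the number of items; with a
  24-item bank a few percent of spread inflation remains in unanchored
  difficulty estimates (visible as a regression slope slightly above 1
  against generating values). Conditional or marginal estimation would
  remove it but is out of scope.
- The rating-scale family assumes one shared category structure; items
  whose categories genuinely behave differently need a partial-credit
  model, which this package does not fit.
- Misfit screening is single-pass by design; iterative purification can
  change the retained set on borderline items.
- CAT item selection has no exposure control or content balancing; for a
  low-stakes satisfaction survey these are unnecessary, for high-stakes
  testing they are not optional.
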