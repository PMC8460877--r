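---
title: "Linking and equating alternate test forms with neatlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking and equating alternate test forms with neatlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neatlink)
library(dplyr)
```

## The problem

Two alternate forms of a dichotomously scored test — here, a reading
comprehension instrument for children in the early school grades — cannot be
compared score-for-score unless they are placed on a common scale. neatlink
implements the full common-item nonequivalent groups (NEAT) workflow: each
group of examinees takes one form plus a shared internal anchor block, both
forms are calibrated separately under a unidimensional two-parameter logistic
(2PL) model, the anchor items identify the affine transformation between the
two latent scales, and raw scores are converted between forms by true-score
or observed-score equating. Age-conditional percentile tables then turn
equated raw scores into normative statements.

## The model and its assumptions

The 2PL gives the probability of a correct response to item $j$ at ability
$\theta$ as

$$P_j(\theta) = \frac{1}{1 + \exp\{-a_j(\theta - b_j)\}},$$

with discrimination $a_j > 0$ and difficulty $b_j$. We use the pure logistic
metric ($D = 1$, no 1.7 normal-ogive constant), matching maximum-likelihood
logit calibration; discriminations quoted elsewhere in the normal metric
differ by that factor. The model assumes unidimensionality and local
independence — responses independent given $\theta$ — which is exactly what
the bivariate residual scan (below) interrogates, since items nested within
the same text are the natural suspects for violations.

**Calibration.** `fit_2pl()` maximizes the marginal likelihood by
Bock–Aitkin EM on a fixed quadrature grid (default 61 equally spaced nodes
on $[-5, 5]$ with standard-normal weights renormalized to 1). The
standard-normal prior identifies each form's scale as mean 0, SD 1. The
M-step updates each item by Fisher scoring with step halving, so the
recorded log-likelihood trace is non-decreasing; convergence is declared
when the largest absolute parameter change falls below $10^{-4}$ (at most
500 cycles; non-convergence is flagged, not thrown). Standard errors come
from the empirical cross-product of per-examinee score vectors at
convergence. Items observed all-correct or all-incorrect are unidentified
and are excluded with a report. Missing responses within a taken form are
scored incorrect, the instrument's scoring convention; set
`na_as_incorrect = FALSE` to treat them as ignorable instead.

**Per-item reliability** is reported as $a^2 / (a^2 + \pi^2/3)$ — the share
of latent-response variance explained by ability under a logistic link with
standard-normal ability. It is 0 for a non-discriminating item and
approaches 1 as $a$ grows.

## Local independence diagnostics

For every item pair the four response-pattern counts are compared with their
model expectations, integrated over the ability distribution:
$E_{xy} = n \sum_k w_k P_i^x (1-P_i)^{1-x} P_j^y (1-P_j)^{1-y}$, and each
cell is standardized as $z = (O - E)\big/\sqrt{E(1 - E/n)}$ — the binomial
standardization, so each cell's $z$ has unit variance under the model. A
form with $J$ items yields $4\binom{J}{2}$ cells. Because that is thousands
of correlated tests, the flagging cutoff is Bonferroni-adjusted: the
two-tailed normal critical value at $\alpha / J$ (about $|3.42|$ for an
81-item form at $\alpha = 0.05$, $|3.47|$ for 95 items). Cells whose
expected proportion falls outside $(10^{-6}, 1 - 10^{-6})$ are excluded and
counted rather than divided by. Expected counts use the marginal
(quadrature-integrated) probabilities, not probabilities at point ability
estimates.

## Item selection under the anchor-ratio rule

An anchor block should be at least ~20% of the full form for stable
linking, so 9 anchors cap a form at $\lfloor 9/0.2\rfloor = 45$ items, 36 of
them form-specific. `select_items()` fills per-text, per-question-type
quotas (the packaged default keeps 33 unique items per form over seven
texts, identical quotas for the two members of each text pair) by a
deterministic greedy rule: within a cell, rank by $a$ descending; when two
candidates sit within 0.05 on $a$, prefer the one whose $b$ falls in the
difficulty stratum — $(-\infty,-1]$, $(-1,1]$, $(1,\infty)$ — least covered
so far within the text; break remaining ties by item id. The rule is a
reproducible embodiment of "most discriminating, heterogeneous in
difficulty"; it is not claimed to be the original authors' tie-break, which
is not documented. Anchors are always retained, and infeasible quotas abort
with the offending text and type named.

## Linking

With anchor estimates on both scales, the transformation
$\theta_{to} = A\theta_{from} + B$ (items map as $a^* = a/A$,
$b^* = Ab + B$) is estimated four ways: mean-sigma and mean-mean from
moments of the anchor parameters, and the two characteristic-curve methods —
Haebara (squared ICC differences summed over items then integrated) and
Stocking–Lord (squared TCC difference integrated). The classic
non-symmetric criteria are used, evaluated on the to-form scale with the
grid's standard-normal weights; the optimizer is Nelder–Mead from the
mean-sigma start polished by BFGS. On anchors related exactly affinely all
four methods recover $(A, B)$ to $10^{-4}$ (a tested invariant).
Coefficient standard errors are parametric-bootstrap (default 500
replicates, seeded): anchor estimates are resampled from independent
normals at their standard errors and the linking re-solved. The delta
method was not used because it needs the full parameter covariance, which a
two-separate-calibrations pipeline does not naturally expose; bootstrap SEs
are method-agnostic but not numerically identical to published delta-method
values.

## Score equating

**True-score equating** inverts the from-form test characteristic curve at
each interior integer score (bracketed root finding, $10^{-9}$ tolerance —
the 2PL TCC is strictly monotone) and evaluates the to-form TCC at the same
ability; endpoints map $0 \to 0$ and $n \to n$. With no guessing parameter
the TCC is invertible on the whole open score range, so no extrapolation
region is needed.

**Observed-score equating** builds each form's model-implied ("synthetic
population") raw-score distribution by integrating the Lord–Wingersky
recursion over the grid weights, then maps scores equipercentile-wise:
midpoint percentile ranks $PR(s) = F(s-1) + p(s)/2$ and a piecewise-linear
quantile of the target, no presmoothing, equivalents clamped to the target
score range. The population weights default to the grid's standard-normal
weights; pass empirical (EAP-based) weights for an observed population.

Equated values are kept at full precision; rounding (half-up — values above
the .50 decimal go up) happens exactly once, at norm-table construction or
lookup.

**Known limitation.** The equipercentile map is only as stable as the mass
behind it: at scores whose population probability is below ~$10^{-4}$
(the extreme tails), clamping and continuization make the from→to and
to→from maps visibly non-inverse (deviations beyond one score point),
while interior scores round-trip within a tenth of a point. The symmetry
test therefore evaluates scores with percentile ranks in $[0.5\%, 99.5\%]$.

## Age-specific reference intervals

`fit_reference()` searches 44 candidate mean functions of age: the 8
one-term fractional polynomials over powers
$\{-2, -1, -0.5, 0 (\log), 0.5, 1, 2, 3\}$ and the 36 unordered two-term
pairs including repeated powers (a repeated power $p$ contributes $x^p$ and
$x^p \log x$). Plain linear growth is FP1(1), the quadratic is FP2(1,2),
cubic-type shapes are covered by pairs such as FP2(2,3), and the
inverse-squared family enters through power $-2$ — including FP2(−2,−2),
$\beta_0 + \beta_1\,\mathrm{age}^{-2} + \beta_2\,\mathrm{age}^{-2}\log(\mathrm{age})$.
A three-term cubic polynomial is not in the fractional-polynomial family;
adding it would make the roster 45, so the 8 + 36 = 44 composition is the
one shipped (as editable configuration, not code). Candidates are fitted by
least squares, ranked by $R^2$, and the winner's residuals feed the spread
model: constant SD by default, or SD linear in age via the
$\sqrt{\pi/2}$-scaled absolute-residual regression. Percentile curves are
$\hat\mu(\mathrm{age}) + z_p \hat\sigma(\mathrm{age})$; with a constant or
positive linear SD they cannot cross inside the fitted range (checked).
Norm tables refuse to extrapolate beyond the fitted ages (integer boundary
ages of a continuous fitted range are allowed) and round half-up once.

The instrument's published age-norm table ships with the package
(`published_norm_table()`); `score_to_percentile_band()` returns the highest
tabulated level at or below a score, and `equated_norm_lookup()` first
converts a score from the other form, rounds half-up, then looks it up —
e.g. an equated 15.5963 at age 8 rounds to 16 and lands on the 75th
percentile of that table.

## The synthetic study generator

`generate_neat_study()` is the package's ground-truth instrument. Defaults
emulate the study conditions the pipeline targets: groups of 427 and 321
examinees; 33 unique items per form (over seven texts with fixed
question-type quotas) plus 9 shared anchors; generating discriminations
uniform on $[0.6, 2.0]$ and difficulties on $[-2.5, 2.5]$ (anchors on
$[-1.5, 1.5]$ — anchor blocks are written to be of moderate difficulty);
integer ages 6–12 with mean 9.1, SD 1.0, and a Gaussian-copula correlation
of 0.6 with ability (comprehension grows across grades 2–5; the exact value
is a package choice, the study reports no such correlation). True item
parameters live on the to-form's scale, where the to-group is standard
normal; the from-group is $N(B, A)$ there, so linking the calibrated forms
recovers the configured `true_link` — default $(0.91536, -0.21297)$, the
mild nonequivalence estimated between the study's randomly assigned groups.
All randomness flows from one integer seed; equal configs are bit-identical.

What the generator does **not** emulate: within-text response dependence
(testlet effects), differential item functioning, school-level clustering,
or examinee non-response patterns. Passing tests on this generator
therefore validate the estimation and equating machinery, not robustness to
those real-data features.

A sobering, tested fact about the design itself: with 9 anchors and groups
of a few hundred, the sampling SD of the Stocking–Lord slope is about 0.08,
so single-study linking coefficients carry an irreducible uncertainty of
roughly $\pm 0.15$ at 95% confidence — replicate-level recovery of the true
slope within $\pm 0.1$ succeeds only about 60–70% of the time no matter the
estimator. Anchor precision, not the algorithm, is the binding constraint.

## Problem sizes used in the test suite

Property tests run at sizes chosen to make Monte-Carlo error small relative
to the asserted bounds while keeping the suite quick: parameter recovery at
$n = 2000$ with 40 items; Yen Q1 null calibration with 150 refitted
replicates at $n = 1500$, 15 items; residual-scan null behavior pooled over
10 replicates of a 20-item, $n = 2000$ form; end-to-end link recovery over
10 replicate studies at the default 427/321 scale; exhaustive
Lord–Wingersky verification up to $2^{12}$ patterns.

## Numerical choices

Quadrature: 61 nodes on $[-5, 5]$ (information figures cover $[-4, 4]$ with
margin). EM: tolerance $10^{-4}$ on parameters, 500-cycle cap, Fisher
scoring with step halving in the M-step. Characteristic-curve optimizers:
criterion tolerance $10^{-8}$ or better, mean-sigma start. TCC inversion:
$10^{-9}$ in $\theta$. Yen Q1: 10 ability deciles, $df = 8$; the item under
test is excluded from its own grouping score and its expected proportion is
the posterior-expected ICC — plugging a shrunken point-EAP that includes
the item inflates the statistic's null rejection rate to ~0.95, while the
leave-one-out form is calibrated (~0.05, verified by simulation with
refitting). Degenerate inputs: zero-spread anchors, point-mass score
distributions, all-missing examinees and out-of-range ages all raise typed
conditions or flagged results rather than silent numbers.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- list(
  simulate = list(n_from = 427, n_to = 321, seed = 7),
  selection = FALSE,          # the default layout is already the reduced form
  linking_method = "stocking_lord",
  out_dir = "equating_run", seed = 7)
manifest <- run_pipeline(cfg, verbose = TRUE)
```

The run writes calibrated banks, residual scans, the four-method linking
table, both equating tables, the fitted norm table, and a manifest with
file hashes — every inter-stage artifact is a file, so stages can be
re-examined independently.
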