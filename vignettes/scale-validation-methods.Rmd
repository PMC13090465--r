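---
title: "Models and methods behind scalenorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scalenorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalenorm)
```

scalenorm validates ordinal screening questionnaires the way modern
instrument-battery studies do: each subscale is calibrated with a graded
response model, a fixed rubric judges its measurement properties, and a
normative table translates crude summed scores into standardized scores
with severity bands. This vignette explains the models, the tunable
parameters, and the numerical and design choices, and states what the
synthetic cohorts used in the test suite do and do not establish.

## The response model

For an item $j$ with $K_j$ ordered categories $0, \dots, K_j-1$, the
graded response model (GRM) specifies cumulative boundary curves
$P(X_j \ge k \mid \theta) = \sigma\!\big(a_j(\theta - b_{jk})\big)$ with
the logistic $\sigma$, discrimination $a_j > 0$ and strictly increasing
thresholds $b_{j1} < \dots < b_{j,K_j-1}$ on the latent-trait scale.
Category probabilities are differences of adjacent boundary curves. The
graded rating scale variant (GRSM) constrains all items of a subscale to
one shared step vector $t_k$ plus an item location $d_j$
($b_{jk} = d_j + t_k$); it is available via `model = "grsm"` and is
identified by fixing $d_1 = 0$ alongside the standard-normal trait.
We keep the pure logistic metric inside the model — the 1.702
logistic-to-probit constant enters only when discriminations are
converted to standardized factor loadings,
$\lambda_j = a^*_j/\sqrt{1 + a^{*2}_j}$ with $a^*_j = a_j/1.702$.

Binary items are the $K_j = 2$ special case and run through the same
code path, where the model coincides with the two-parameter logistic
model.

## Estimation

Calibration is marginal maximum likelihood with a standard-normal
latent prior, integrated on an equally spaced grid of 61 nodes on
$[-6, 6]$ with renormalized normal weights (configurable;
`quadrature_grid()`). The trait distribution is fixed at mean 0, sd 1
for identification. EM alternates an E-step over collapsed response
patterns (identical to per-person E-steps, just faster) with per-item
M-steps by BFGS using analytic gradients in the reparameterization
$(\log a,\ b_1,\ \log \Delta b)$, which preserves threshold ordering by
construction. The M-step never accepts a worse objective value, so the
marginal log-likelihood trace is nondecreasing — asserted on every fit.
Defaults: tolerance $10^{-5}$ on the log-likelihood change, at most 500
iterations; non-convergence is flagged and warned about, never silent.
Start values are $a = 1$ and inverse-normal transforms of the observed
cumulative category rates.

Items showing a single observed category cannot be calibrated and
produce an error naming the item, so the caller can collapse categories
or drop the item deliberately.

Person scores are expected a posteriori (EAP) means with posterior sds
on the same grid. The summed-score distribution and
$E[\theta \mid S = s]$ come from the Lord–Wingersky recursion evaluated
at each node and prior-weighted; the recursion is tested against
exhaustive pattern enumeration to $10^{-10}$.

## Fit evaluation

**Global fit.** Full-pattern chi-square tests are infeasible for these
tables, so the package uses a limited-information quadratic form on
univariate category margins plus bivariate cross-product moments
(`m2_statistic()`). With the orthogonal-complement weight matrix
$C = \Xi^{-1} - \Xi^{-1}\Delta(\Delta'\Xi^{-1}\Delta)^{-1}\Delta'\Xi^{-1}$
(model-implied moment covariance $\Xi$, finite-difference Jacobian
$\Delta$), the statistic is asymptotically chi-square with
$s - q$ degrees of freedom at any consistent estimate. For a GRM this
gives $J(J-1)/2 - J$ degrees of freedom, so at least four items are
required. RMSEA, CFI and TLI follow the usual formulas against an
independence baseline fitted on the same margins
(`baseline_m2()`, $df_b = J(J-1)/2$); SRMR is the root mean square
difference between observed and model-implied inter-item Pearson
correlations. In null simulations at $n = 2000$ the statistic rejects at
close to its nominal 5% level.

**Infit.** Item and person infit mean squares are information-weighted
mean-square residuals at the EAP estimate. Because the EAP borrows the
item's own response and shrinks toward the prior, infit is structurally
below 1 for short subscales — around 0.75–0.9 for 5–7 item scales, and
0.9–1.0 for 20-item scales. This is a property of the estimator, not
misfit; the rubric's [0.5, 1.5] band is comfortably wide for it, and the
package's null-calibration battery (20 items) verifies the tighter
[0.9, 1.1] behaviour.

**Local dependence.** Residual correlations correlate
$x_{nj} - E[X_j \mid \hat\theta_n]$ across persons. The raw version of
this statistic has a well-known systematic negative shift (about
$-0.2$ for five items) because all residuals share the one estimated
trait; the default therefore centers the matrix by its mean off-diagonal
value, leaving locally independent data near zero while preserving the
contrast that flags dependent pairs (a duplicated item is flagged at the
matrix maximum). The uncentered matrix is available with
`method = "q3"`.

**Scalability and monotonicity.** Loevinger's $H_{ij}$ is computed as
the ratio of the observed covariance to the maximum covariance
attainable under the items' margins (the comonotone coupling), pooled
into item and scale coefficients; this equals the familiar
1 − observed/expected Guttman error form and is exactly 1 on error-free
Guttman data. Monotonicity is checked on rest-score groups of at least
`minsize` members (default $n/10$, floor 50, for $n \ge 500$; else
$n/5$, floor 10): every ordered pair of groups must show nondecreasing
item-step probabilities. Drops larger than `minvi` (default 0.03) are
candidates; a candidate becomes a recorded violation only when its
one-sided two-proportion $z$ exceeds the multiplicity-corrected critical
value $\Phi^{-1}(1 - \alpha/\#\text{comparisons})$ (default
$\alpha = 0.05$; roughly $z > 3.3$ at $n = 2000$). An item at $n=2000$
undergoes over a hundred ordered comparisons, so an uncorrected screen
records spurious single drops in about half of all null datasets; the
corrected screen leaves model-consistent data clean while a reversed
item still produces dozens of violations with $z$ far beyond any
threshold. The per-item criticality score
$\mathrm{crit} = \mathrm{round}(50\sum \text{mag} + 10\sum (z - z_c))$
is a deterministic weighting of count, magnitude and significance:
single borderline drops score in single digits, 40–90 marks a borderline
item, systematic reversals score in the hundreds. Only band membership
(< 40 acceptable, 40–90 borderline, > 90 failing) should be interpreted,
not digits.

## The rubric

`compile_verdict()` combines four factor-analysis criteria and
reliability:

1. *Unidimensionality*: at least two of {RMSEA ≤ 0.06 (values in
   (0.06, 0.08] count but are labelled "acceptable"), SRMR ≤ 0.08,
   TLI ≥ 0.95 and CFI ≥ 0.95 jointly}. Treating TLI/CFI as one member
   keeps the menu at exactly three entries, which reproduces the
   published failing pattern for a weak subscale (only RMSEA in range →
   1 of 3 → fail).
2. *Local independence*: all $|r| < 0.2$, or third quartile $< 0.37$;
   flagged pairs are always listed.
3. *Monotonicity*: every $H_i > 0.3$ (strict) and no violation with
   crit > 90; 40–90 annotated acceptable. The "adequate looking graphs"
   escape is a manual override flag, never automatic.
4. *Global fit*: unidimensionality passed and all item infits in
   [0.5, 1.5].

Boundary readings are strict where the wording is strict: reliability
"exceeds" 0.7/0.8/0.9, so exactly 0.7 rates inadequate. The overall
"supported" flag requires all four criteria plus at-least-positive
reliability; whether reliability gates the flag is configurable
(`require_reliability`), since property reports often discuss the two
separately. Missing components yield "incomplete", never a silent pass.

## Normative references

Within each norm group (age-group × gender by default; gender pooled
with a message when a cell is below `min_group = 30`, and still-small
groups flagged unstable), person T-scores standardize the EAP trait to
mean 50, sd 10. Crude scores are linked model-based:
$\theta(s) = E[\theta \mid S = s]$ from the summed-score posterior, then
standardized against the group's trait distribution. Model-based linking
is defined for unobserved sums and monotone by construction; empirical
linking of observed means would be undefined at unattained scores.
Percentiles use the mid-probability convention
$100\,(P(S < s) + \tfrac12 P(S = s))$ on the group's observed sums.
Severity bands follow the PROMIS convention on the raw T: minimal
(< 55), mild (55–59), moderate (60–69), severe (≥ 70). For display the
T value is truncated within its band's nominal range (slope-one
rescaling with floor 20 and ceiling 80 at the outer bands) — band
membership is decided before truncation and never changed by it, and
machine outputs always retain the raw values. The truncation rule is a
documented presentation choice; other within-band rescalings would be
defensible.

## Synthetic cohorts: what they emulate

`make_fixture_cohort()` reproduces the statistical structure of a
nationwide screening survey: ordinal 0–2/0–3 Likert and binary yes/no
items generated from a GRM; a standard-normal trait with optional
stratum mean shifts; stratification by age band (6–9, 10–13, 14–18,
toddler) and gender with exact design counts; sample sizes spanning the
study range (137, 200, 1356); and no item-level missingness.
Discriminations sit in ranges mapping to factor loadings of roughly
0.55–0.93 and thresholds are right-shifted into $[-2.5, 2.5]$, as
community symptom data are; the `psc17-like` preset gives each subscale
its own trait loading 0.8 on a common factor, so subscales correlate
while each stays unidimensional. The `mchat-like` preset plants eight
weak/extreme items at the positions reported problematic for that
screener, reproducing the failing-monotonicity pattern. A single root
seed expands into per-stage substreams, so adding an item leaves earlier
items' draws untouched and any preset regenerates byte-identically.

What passing on these cohorts does *not* show: real questionnaire data
bring multidimensionality, informant effects, differential item
functioning across demographic groups, and non-random sampling — none of
which the generator produces. Verdicts on synthetic cohorts validate the
machinery, not any instrument.

## Problem sizes used in the test suite

The package's property battery fits 20 replicate cohorts of $n = 2000$
on the 20-item four-category preset — chosen as the scale length where
the null infit band [0.9, 1.1] is informative — and checks parameter
recovery (RMSE of $\hat a$ and $\hat b$), EM monotonicity, the M2-type
rejection rate, residual correlations and monotonicity simultaneously.
Module tests use $n$ between 200 and 5000 with single fixed seeds.
These sizes were chosen to make Monte-Carlo error small relative to
every asserted bound while keeping the suite quick on one CPU.

## Known limitations

- Only unidimensional GRM/GRSM per subscale: no bifactor or
  multidimensional structures, no DIF or measurement-invariance tests.
- The M2-type statistic needs at least four items and moderate $n$;
  asymptotics at $n \approx 200$ with many binary items are rough.
- Severity bands are interpretive conventions, not clinically
  calibrated cutoffs; norm groups below 30 members are flagged rather
  than suppressed.
- `reliability` uses Pearson covariances on raw integer scores for
  $\alpha$; polychoric variants are out of scope.
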