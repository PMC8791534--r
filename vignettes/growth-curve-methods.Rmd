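---
title: "Modelling lobar gray-matter growth with fractional polynomials"
author: "neurogrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lobar gray-matter growth with fractional polynomials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogrowth)
```

## The model

Cortical gray-matter (GM) volume grows explosively in infancy, peaks in
late childhood, and declines through adolescence. Capturing that whole arc
in one mean curve is the central statistical problem this package solves.
A conventional quadratic in age is far too stiff for the infant phase, so
the mean trajectory is a second-order *fractional polynomial* (FP2) of age:
two transforms $g_1, g_2$ of age drawn from the standard power set

$$S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\},$$

with power $0$ read as $\log(a)$ and a repeated power $p$ read as
$(a^p,\ a^p \log a)$. That yields $\binom{8}{2} + 8 = 36$ candidate shapes,
one of which is the quadratic $(1, 2)$, so the conventional model is
subsumed rather than imposed. Age is always measured in years
(months / 12) and never shifted or rescaled: the youngest observable age
(5 months) is positive, so logs and negative powers are safe, and
derivatives convert to per-month units by dividing by 12.

For a scan of child $i$ at center $C$ and visit $t$,

$$\mathrm{volume}_{iCt} = f(\mathrm{sex}_i, \mathrm{age}_{it})
  + u_{iC} + v_i + \varepsilon_{iCt},$$

where $f$ is the FP2 curve *fully interacted with sex* (sex-specific
intercept and two sex-specific age coefficients — six fixed effects), and
$u$ and $v$ are random intercepts for study center and for subject nested
within center. All fits use full maximum likelihood, not REML, so
likelihood-based criteria stay comparable when the fixed part changes
(which it does in the income analysis). The implied marginal covariance is
$V = \sigma^2_c Z_c Z_c' + \sigma^2_s Z_s Z_s' + \sigma^2_e I$.

The ML fitter is written for this structure: the likelihood is profiled so
only the two variance ratios $\lambda_s = \sigma^2_s/\sigma^2_e$ and
$\lambda_c = \sigma^2_c/\sigma^2_e$ are optimized numerically (Nelder-Mead
on the log scale, multi-start, with a final snap of each ratio to the zero
boundary when the profile is flat there). Because subjects are nested in
centers, $V^{-1}x$ is an $O(n)$ operation — Sherman-Morrison per subject
followed by a rank-one update per center — which is what makes the
bootstrap suites below affordable. The test suite checks the fitter
against a dense multivariate-normal likelihood oracle on small instances
and against lme4 on moderate ones.

### Model selection

`gm_trajectory()` fits all 36 candidates per lobe on identical rows and
keeps the minimizer of the selection criterion (BIC by default). All
candidates have the same parameter count (6 fixed + 3 variance), so
-2LL, AIC and BIC must rank them identically; the function *asserts* this
on every run instead of silently choosing one criterion. Exact ties break
by lower -2LL, then lexicographically smaller powers. Candidates that fail
to converge are excluded and recorded in the selection table.

### Growth rates and peak ages

Growth is the analytic derivative of the fitted curve, reported in
mm^3/month (`fp_derivative()` divided by 12) and as a percentage of the
predicted volume at the same age. Peak age is located by a 0.01-year grid
scan refined by bisection on the derivative's sign change; monotone fits
return the boundary age with a flag. For the $(0,1)$ basis the interior
peak equals $-\beta_1/\beta_2$ in closed form, which the tests exploit.

### Volume-for-age percentile charts

Charts describe the *population* spread, so residuals are taken against
the fixed-effects prediction only — center, subject and scan variability
all stay in the residual. Squared residuals are then modelled as a
first-order FP of age: for each single power $q \in S$ an ordinary
least-squares fit of $r^2$ on $(1, g_q(a))$, selected by residual sum of
squares, separately per sex. "First-order function of age" is read as a
first-order FP because that keeps the variance model in the same family as
the mean model; when every candidate's fitted variance dips non-positive
somewhere on the support, the fallback chain is linear-in-age, then
constant (which always succeeds), and a floor of $10^{-6}$ times the mean
squared residual keeps the SD defined. Percentile curves are then

$$P_q(a) = \hat f(\mathrm{sex}, a) + z_{q/100}\,\widehat{SD}(a),$$

a normal-quantile construction: the median is the mean curve, bands are
symmetric, and curves are strictly monotone in level. The package does not
implement LMS (Box-Cox) chart methodology; skewness in real volume
distributions is a known limitation of the normal construction.

### The low-income gap

Family income arrives as one of nine brackets; the bracket midpoint
divided by the federal poverty guideline for the family size gives the
income-to-poverty ratio, and "low income" means a ratio below 200% of the
poverty level (a 100% threshold reproduces the strict-poverty variant).
The bundled guideline table is the 2001 HHS schedule (family sizes 1-8,
extended by the per-person increment beyond the table); it is a versioned
CSV and user-replaceable, since the study period spans several guideline
years. A subject's first non-missing report is carried to all scans; rows
with missing income are dropped from income models only — never from
trajectory fitting.

The augmented model re-estimates the selected trajectory (basis inherited,
not re-selected) plus three income terms: a low-income indicator and its
interactions with the two age transforms. The terms are not interacted
with sex. The age-varying gap is
$\Delta(a) = \gamma_0 + \gamma_1 g_1(a) + \gamma_2 g_2(a)$.

Inference uses a cluster bootstrap: subjects are resampled with
replacement within their center, keeping each drawn subject's full scan
history, with fresh ids for duplicates. Subject-level resampling respects
within-child correlation, the dominant dependence; with only six centers,
resampling centers themselves is too coarse, and cluster-robust sandwich
standard errors (also provided) carry a small-G caveat. Intervals are
bias-corrected (BC, no acceleration): $z_0 = \Phi^{-1}(\#\{\Delta^* <
\hat\Delta\}/B)$ shifts the percentile levels to $\Phi(2 z_0 \pm 1.96)$.
The earliest detection age is the smallest age on a half-year grid
(0.5-20.5 y) whose interval excludes zero. Replicates that fail to
converge are redrawn, capped at $5B$ draws.

## The synthetic cohort generator

There is no public microdata at desk scale, so the package carries a
generator that reproduces the study's two-protocol accelerated
longitudinal design: a child/adolescent arm (399 subjects, ages 59-251
months, 1-3 scans about two years apart, six centers) and an
infant/toddler arm (87 subjects, ages 5-102 months, 1-7 scans at 3-12
month intervals, two of the six centers); 48.1% boys, 26% of families
below 200% FPL, 2.6% missing income, birth weight drawn truncated-normal
$N(3541, 472^2)$ above 1500 g. Scan-count probabilities follow the
study's margins; scheduled scans that would exceed an arm's age maximum
are dropped, so a default cohort carries ~1015 scans rather than the
study's 1057.

The true female curve for every lobe uses the $(0,1)$ basis
$V_f(a) = \beta_0 + \beta_1 \log a + \beta_2 a$ — the simplest FP2 with an
inverted-U and rapid infant growth. `calibrate_truth()` solves the
coefficients exactly from three constraints per lobe: the peak age, the
peak volume, and the relative growth rate at age 5 months. Reported
anchors fix the frontal peak at 9 y and occipital at 6 y, and infant
growth at 2.1 (frontal) and 3.7 (parietal) %/month; the remaining anchors
(temporal peak 7.5 y, parietal 7 y, temporal 2.6 and occipital 3.2
%/month, peak volumes 230/170/150/70 thousand mm^3) are defaults chosen
once as plausible for lobar GM. Boys are a constant 1.10 multiple of the
female curve (the ramp-up of the sex difference over infancy is omitted so
the sex effect is a single identifiable number). The income gap is
$\Delta(a) = \gamma_1 \log a + \gamma_2 a$ with no constant — gaps vanish
toward birth — solved so that $\Delta$ hits the reported coefficient at
each lobe's detection-onset age and the reported percent deficit of
$V_f(20)$ at age 20.

Noise defaults: center SD 1.5% and subject SD 7% of the lobe peak volume,
and scan-level SD $3\% \cdot \mathrm{peak} \cdot (1 + 0.01a)$, mildly
increasing in age so the variance-curve stage has something to find.
Income status acts on the mean only and is constant within subject.

What the generator does *not* emulate: segmentation error and scanner
differences, attrition, income dynamics, skewed volume distributions, and
any sex difference in curve shape. Tests passing on this generator
therefore validate the estimators under the model's own assumptions (plus
mild variance misspecification), not robustness to real MRI artifacts.

## Numerical and design choices

* **Estimation.** ML throughout; variance ratios log-parameterized with
  multi-start Nelder-Mead and a zero-boundary snap; `k_params` counts all
  three variance components even at the boundary.
* **Bootstrap refits.** The FP powers are frozen during replicates
  (re-selection per replicate is disabled by default for runtime);
  replicate fits warm-start at the full-data variance ratios and reuse the
  full-data design rows at the matrix level.
* **BC quantiles** use type-6 sample quantiles; the median-bias proportion
  is clamped to $[1/(B+1), B/(B+1)]$ to keep $z_0$ finite.
* **Degenerate inputs.** Non-positive ages, unknown sex codes and missing
  schema columns are rejected at read time with row numbers; single-cluster
  robust covariance requests are errors; variance curves always succeed
  via the constant fallback.
* **Finite-center floor.** With six centers the fixed intercept absorbs
  the mean of six center draws, leaving a ~0.6%-of-volume offset that no
  subject count removes; consistency checks of the mean curve therefore
  switch the center variance off. Real-data intercepts carry the same
  caveat.
* **Power at study scale.** Under the default noise the per-dataset SE of
  the fitted gap at the frontal onset age is roughly 2700 mm^3 — about
  three-quarters of the embedded onset-age gap itself. Detection is
  power-limited and typically trails the embedded onset by one to three
  years, and single-cohort gap estimates scatter widely around the truth;
  the recovery checks therefore average 20 seeded replicates.

## Problem sizes used by the test and acceptance suites

Simulation-based checks are sized to known Monte-Carlo behavior: recovery
of embedded quantities averages 20 default cohorts (486 subjects each);
bootstrap-coverage checks run 100 small cohorts (100 subjects) at B = 200;
percentile-band coverage uses one 3000-subject cohort; selection
consistency uses 20 cohorts of 300 subjects under low noise, meaning every
variance component at or below 0.5% of the peak volume — shape
discrimination is limited by the between-subject SD, not the scan-level
residual, and at 300 subjects the nearest rival bases ((0.5, 0.5) and
(0, 0.5)) sit within a few BIC points of the generating (0, 1) basis
until the subject SD falls well below 1% of the signal. These sizes are
the package's validation design choices.

## Limitations

The package estimates associations, not causal effects of income; the
normal-quantile charts ignore skewness; the two-arm design identifies ages
4.9-6.2 y in both protocols but infancy only through two centers, so
center and protocol are partially confounded there; and with six centers,
center-level inference (robust SEs) is anchored on very few clusters —
the bootstrap operates within centers, not across them.
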