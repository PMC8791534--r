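# neurogrowth

Growth-curve analysis of lobar gray-matter (GM) volumes from infancy
through early adulthood, for researchers modelling structural brain
development in accelerated longitudinal MRI cohorts and for anyone who
needs volume-for-age reference charts or income-disparity estimates from
such data.

## What it computes

The mean trajectory of GM volume in each cortical lobe (frontal, temporal,
parietal, occipital) is a second-order fractional polynomial (FP2) of age
inside a three-level linear mixed model — scans nested in subjects nested
in study centers:

    volume_iCt = f(sex_i, age_it) + u_iC + v_i + e_iCt

`f` uses two age transforms with powers from the standard set
{-2, -1, -0.5, 0, 0.5, 1, 2, 3} (0 = log), fully interacted with sex; all
36 canonical FP2 candidates are fitted by maximum likelihood and ranked by
BIC (with equal parameter counts, -2LL, AIC and BIC agree — the package
asserts it). On top of the fitted trajectory the package provides:

* **Growth rates** — analytic derivatives in mm³/month and %/month, and
  peak ages (closed form −β₁/β₂ for the (0,1) basis), with bootstrap
  male–female contrasts;
* **Percentile charts** — sex-specific volume-for-age curves
  `P_q(age) = mean(age) + z_q · SD(age)`, where SD(age) comes from a
  first-order FP fit to squared population residuals;
* **Income gaps** — the trajectory re-estimated with a low-income
  indicator (family income below 200% of the federal poverty guideline,
  computed from bracket midpoints and family size) plus its interactions
  with the two age transforms, giving an age-varying gap Δ(age) with
  bias-corrected 95% cluster-bootstrap intervals and the earliest age at
  which the interval excludes zero;
* **A calibrated synthetic cohort generator** reproducing the
  two-protocol design (399 child/adolescent + 87 infant/toddler subjects,
  six centers, ~26% low-income, ~1050 scans) with known true curves, so
  every stage has a known-truth test bed.

## Worked example

```r
library(neurogrowth)

truth <- calibrate_truth()                      # known true curves
scans <- generate_cohort(truth, seed = 1)       # default two-arm cohort
scans <- derive_low_income(scans)               # income-to-FPL ratio + flag

traj <- gm_trajectory(scans, "frontal")         # 36-candidate FP2 selection
traj
#> Gray-matter growth trajectory: frontal lobe
#>   FP2 basis powers (0, 1), selected by BIC
#>   n = 1016 scans from 486 subjects; ages 0.43 - 20.6 y
#>   -2LL: 22127.469  AIC: 22145.469  BIC: 22189.782
#> Fixed effects:
#>       sexF       sexM    sexF:g1    sexM:g1    sexF:g2    sexM:g2
#> 211397.338 227146.402  19196.360  20625.458  -2589.124  -2164.606
```

The selection lands on the (0, 1) basis — volume = b0 + b1·log(age) +
b2·age — which is the generating shape; the six coefficients are the
sex-specific intercepts and age terms (boys' curves sit ~10% above girls',
the generator's embedded sex effect). Growth rates and the peak:

```r
growth_curve(traj, "F", c(0.45, 2, 10))[, c("age_years", "rate_mm3_per_month",
                                            "rate_pct_per_month")]
#>   age_years rate_mm3_per_month rate_pct_per_month
#> 1      0.45         3339.12111         1.71321506
#> 2      2.00          584.08799         0.26606902
#> 3     10.00          -55.79067        -0.02428771
peak_age(traj, "F")$age
#> [1] 7.41423
```

Growth at the youngest observed ages runs at ~1.7%/month on this
realization (the embedded truth at 5 months is 2.1) and has fallen by an
order of magnitude by ages 2-4. The fitted
female peak (7.4 y) sits below the embedded 9 y because the sex-only
trajectory marginalizes over the 26% of children carrying the embedded
income deficit. The income model makes that deficit explicit:

```r
gap <- bootstrap_gap(scans, traj, B = 1000, seed = 2)
gap
#> Low-income gap in frontal GM volume (basis powers  0, 1 )
#>   gap coefficients g0/g1/g2:  1769.04  4691.12 -1934.28
#>   bootstrap: B = 1000 , seed = 2 , level = 0.95
#>   earliest detection at 8.5 y: gap -4633.0 mm^3 (CI -8774.5, -688.4)
#>   age_years pct_gap_male pct_gap_female
#> 1       6.5     0.801369      0.8747452
#> 2      20.0     9.083623     10.2109705
```

The gap widens with age, becomes statistically distinguishable from zero
in late childhood (detection at 8.5 y here, vs the embedded onset of
6.5 y — detection is power-limited at this cohort size), and reaches a
~9-10% deficit by age 20 on this realization (embedded truth 6.5-7.1%;
single-cohort gap estimates scatter widely, which is why the acceptance
protocol averages 20 cohorts). Percentile charts come from the same fit:

```r
r  <- residuals(traj, scans)
vc <- fit_variance_curve(r$resid[r$sex == "F"], r$age_years[r$sex == "F"],
                         sex = "F", lobe = "frontal")
chart <- percentile_chart(traj, vc, "F")
plot(chart)          # 5th...95th percentile curves vs age
```

`run_pipeline(run_config(...))` chains all stages per lobe and writes
selection tables, model JSON, growth/chart/income CSVs and a run log to an
output directory.

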