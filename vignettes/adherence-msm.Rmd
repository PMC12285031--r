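---
title: "Adherence, LDL-c trajectories, and weighted causal estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adherence, LDL-c trajectories, and weighted causal estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcmsm)
```

This vignette documents the statistical machinery of `pdcmsm`: what is
modelled, which tunable parameters matter, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where several defensible options existed.

## 1. Adherence as proportion of days covered

The adherence measure is a pure dispensing ratio:

$$\mathrm{PDC} = 100 \times
  \frac{\text{tablets prescribed in the study window}}
       {\text{window length in days}}.$$

There is deliberately **no stockpiling or day-level coverage walk**: tablets
are not carried between windows, because the measure is defined as a ratio
of totals, and because interval windows (below) partition time, so
carrying supply across a boundary would double-count. A consequence worth
knowing: PDC over a union of windows is the length-weighted mean of the
interval PDCs, a property the test suite checks.

Values above 100% are retained up to 200% — multi-tablet regimens and early
refills produce them legitimately — and first-year values above 200% flag
the patient for exclusion as a probable data error.

**First-year rules** (`compute_pdc_year1`). The nominal window is 365 days
from the first prescription. The prescription straddling the year boundary
is handled by extending the window to the issue date of the next
prescription when one exists on day ≥ 365 (its tablets and its days both
count), and by dropping the final prescription entirely when the patient
has no later prescription — its coverage period is unobserved, so the
window ends at its issue date and the patient is flagged
(`trailing_script_dropped`). The boundary-extension rule is applied to every
patient with a script at or beyond day 365, which is the reading that makes
the window a deterministic function of the refill stream; it can be
narrowed by pre-filtering records if a stricter reading is wanted. A patient
whose only prescription has no successor has *no* observable coverage
period and gets a missing PDC1 rather than an arbitrary value.

**Categories.** PDC1 is partitioned as `<50`, `[50, 95]`, `>95`. The middle
band is closed at both ends so the three bands are a true partition; the
boundary values 50 and 95 land in the middle band.

**Interval PDC** (`compute_interval_pdc`). For longitudinal analysis,
`PDC_k` is the PDC over the half-open window from time point `k - 1` to
visit `k`, where time point 0 is the *later* of the baseline LDL-c day and
the first prescription day — coverage cannot begin before treatment. All
windows are half-open `[start, end)` on an integer day grid, and a script
issued exactly on a visit day belongs to the following window; this
convention makes windows partition time with no ambiguity at boundaries.

**Exclusions.** "Died within 3 months" is operationalized as death before
day 90, consistent with the 90-day post-discharge rule used for LDL
measures; a death on day 90 or later is retained.

## 2. LDL-c trajectories

The baseline measure is the one closest to the first prescription among
measures within 180 days before it. A measure dated the first-prescription
day itself is accepted as pre-treatment (blood draws typically precede the
prescription within a same-day consultation); duplicate same-day measures
are averaged and flagged. Follow-ups are the earliest measure within 365
days (`year1` mode) or the first three measures within 3652 days
(`longitudinal` mode; fewer than three drops the patient).

Validity filters run **before** selection, at measure level for the
plausibility bounds (values below 1 or above 8 mmol/L removed; exactly 1 or
8 retained, the bounds being strict) and at patient level for treatment
initiation within 90 days after a cardiovascular hospital discharge. The
patient-level reading of the discharge rule is the stricter of the two
plausible readings and is the default; a measurement-level variant is
available via `patient_level = FALSE`.

The outcome scales are the change ratio $Y = LDL_1 / LDL_0$ and the
per-visit fractional reduction $LR_k = (LDL_k - LDL_0)/LDL_0$, linked by
$Y = 1 + LR_1$.

## 3. The synthetic cohort generator

No suitable real cohort can ship with the package, so the generator
produces one with the causal structure the analysis is designed for, with
known coefficients. Fixed confounders: age at first prescription
$\sim N(61, 7.3^2)$ truncated to [40, 79]; female with probability 0.423;
baseline LDL-c $\sim N(3.8, 1.05^2)$ mmol/L truncated to [1, 8]; six
education categories at realistic frequencies; six centres; an additive
genotype with allele frequency 0.15. Visit gaps are Uniform(180, 550) days,
giving a mean time to the third follow-up of about 3 years. Baseline
measures fall 1–30 days before the first prescription.

The longitudinal core is linear-Gaussian with `LR_0 = 0`:

$$PDC_k = \mu + \gamma_P' X + \phi\, LR_{k-1} + \epsilon_k,
  \qquad \epsilon_k \sim N(0, \sigma_P^2),$$
$$LR_k = \beta_k PDC_k + \rho\, LR_{k-1} + \gamma_L' X + \eta_k,
  \qquad \eta_k \sim N(0, \sigma_L^2),$$

with defaults $\mu = 80$, $\sigma_P = 18$ (percent), $\sigma_L = 0.12$,
carry-over $\rho = 0.25$, feedback $\phi = -25$ percent per LR unit (a
larger past reduction raises future adherence), and direct effects
$\beta = (-0.0015, -0.0008, -0.0012)$ per percentage point, summing to
$-0.0035$. Latent PDC is clipped to [0, 150]: inside the plausible observed
range, and with $\mu = 80$, $\sigma_P = 18$ the clipping mass is below
$10^{-3}$, so the Gaussian exposure model used in weighting remains
essentially correctly specified. The feedback strength was set analytically
so that $\mathrm{cor}(PDC_2, LR_1) \approx \phi\,\mathrm{sd}(LR_1)/
\mathrm{sd}(PDC_2) \approx -0.17$ — confounding strong enough that an
unweighted analysis is visibly biased.

Because the system is linear, intervening on the adherence history has the
closed form $E[LR_k(a_1..a_k)] = \text{const} + \sum_j \beta_j
\rho^{\,k-j} a_j$, so the true marginal-structural coefficients are
$b_{kj} = \beta_j \rho^{\,k-j}$ (`true_msm_coef`). With the default
carry-over, the sustained full-adherence contrast at $k = 3$ is
$100\sum_j \beta_j\rho^{3-j} \approx -15$ percentage points of baseline
LDL-c; with $\rho = 0$ it is exactly $100\sum_j\beta_j = -35$.

**Rendering** (`render_prescriptions`). Latent interval adherence is
rendered as refills of 28 tablets at gaps of $28/(PDC/100)$ days (plus
optional day jitter, default SD 1), with the final refill carrying the
remaining tablets so the window total equals
$\mathrm{round}(PDC/100 \times W)$. Dispensed quantities do vary in
practice, and this guarantees the PDC engine recovers the latent value to
within half a tablet per window at zero jitter — a round trip the tests
check at PDC ∈ {10, 25, 50, 75, 100, 140}. A fixed script size alone cannot
offer such a guarantee: achievable ratios would be quantized in steps of
$100 \times 28/W$ percentage points.

**What the generator does not emulate:** dose titration and switching,
competing statins, informative visit timing (gaps are independent of
response), missing-at-random measurement gaps, non-Gaussian adherence
heterogeneity (e.g. abrupt discontinuation), or measurement error in LDL-c
beyond the outcome-equation noise. Passing the recovery tests therefore
shows the estimator is correct *under its stated assumptions*, not that
those assumptions hold in any particular real cohort.

`plant_violations` injects known counts of data-quality pathologies
(implausible dispensing, out-of-range LDL-c, early deaths, post-discharge
initiation) into disjoint patient sets with a returned ledger, so the
filter stages can be tested against exact expected counts.

## 4. Weight estimation and balance

Stage-1 weights are sequential stabilized density ratios with a Gaussian
linear model for each $PDC_k$ given the fixed confounders, the visit time
and the lagged exposure/outcome. The stabilizing numerator is the marginal
density at $k = 1$ and the density given past exposure history at $k > 1$.
Weights are cumulative products across time points (per-k weights target a
different estimand and are not offered). On top of this, the balancing
layer exponentially tilts the weights, $w_i \propto sw_i
\exp(g_i'\delta)$, where $g_i$ collects all standardized
exposure-by-covariate products, and $\delta$ solves the convex dual
$\min_\delta \log \sum_i sw_i e^{g_i'\delta}$ — at the optimum every
weighted exposure–covariate covariance is exactly zero in sample. This is
the direct-balancing construction for continuous treatments in the spirit
of the covariate-balancing propensity score. The non-parametric variant
(`method = "npcbps"`) applies the same tilt from uniform weights, dropping
the parametric density; the plain stabilized weights are available as
`method = "ipw"`.

Numerics: the dual is solved by damped Newton iterations with an analytic
gradient and Hessian, a $10^{-10}$ ridge for safe inversion, and
convergence declared when the largest absolute balance moment falls below
$10^{-9}$. Non-convergence (which essentially requires separation-like
degeneracy) falls back to the untilted stabilized weights with a recorded
warning, never to silent failure. Exposures are *not* balanced against
post-exposure variables — only against each time point's own confounder
set — since balancing an exposure against its own downstream outcomes
would remove the causal signal itself. Weight truncation defaults to none;
percentile winsorization is available and recorded in the `weight_set`.

Balance diagnostics follow the weighted Pearson and weighted Spearman
(rank-then-weighted-Pearson) correlations for every (exposure, covariate)
pair. A covariate passes when the average of its mean absolute Pearson and
mean absolute Spearman correlation across time points is below 0.1 (the
conventional cutoff; configurable). Zero-variance covariates yield `NA`
and are listed as failed, never silently passed. Covariates that fail are
meant to be forced into the stage-2 regression via `forced_covariates`.

## 5. Stage-2 estimation and uncertainty

For each $k$, $LR_k$ is regressed on $PDC_1 .. PDC_k$ simultaneously by
weighted least squares. Because the weights are estimated, analytic
sandwich standard errors would understate or misstate uncertainty in
finite samples; the default is a patient-level nonparametric bootstrap
with the weights re-estimated inside each replicate. Intervals are
normal-theory from the bootstrap SE by default (stable at moderate
replicate counts); percentile intervals are available. Confidence
intervals for contrasts are propagated through the bootstrap replicates of
the whole coefficient vector, preserving their correlation. Replicates
with singular designs are dropped and counted. Per-time-point regressions
are fitted and reported separately (no pooling across $k$), which is the
interpretation that keeps each $LR_k$ model saturated in its own exposure
history.

`intervention_contrast` and `personal_max_contrast` are linear functionals
of the coefficients, so they satisfy exact identities — zero for equal
profiles, additivity over profile chains — that the tests assert at
machine precision.

## 6. Cross-sectional response model

The year-one analysis regresses $Y$ on time-to-follow-up in days with a
quadratic term, optionally a group factor (adherence category or additive
genotype) interacting with both time terms, plus an adjustment set. The
extremum of the fitted curve is at $t^* = -b_t/(2 b_{t^2})$, reported in
weeks ($t^*/7$); its confidence interval is a parametric bootstrap from
the coefficient covariance. A non-positive quadratic coefficient returns a
boundary diagnosis rather than a spurious vertex. Binned group summaries
report raw (unadjusted) means per week bin — with empty bins kept at
$n = 0$ — and the percentage reduction $100(1 - \bar Y)$.

## 7. Validation problem sizes

The test suite validates the pipeline at the scales a single CPU handles
comfortably: exact PDC oracle equivalence on 1,000 randomized histories;
round-trip rendering at six adherence levels and three window lengths;
planted-violation ledgers on a 60-patient cohort; weighting/MSM parameter
recovery over 200 Monte-Carlo replicates of n = 5,000 patients with
48-replicate bootstrap intervals per run; balance efficacy over 100
replicates of n = 5,000; and the zero-confounding equivalence of weighted
and unweighted estimation over 200 replicates of n = 2,000. The end-to-end
raw-tables path (rendered prescriptions through trajectory and adherence
assembly to the weighted fit) runs at n = 3,000 in the acceptance script.

## 8. Known limitations

* The weight model is Gaussian-linear; heavy-tailed or strongly nonlinear
  exposure processes would call for a richer density or the
  `npcbps`-style tilt, and the balance diagnostic — not the density fit —
  is the arbiter of adequacy.
* Exact in-sample balance spends degrees of freedom; with many
  covariates and small n the tilt can inflate weight variability. The
  overfitting floor of the stabilized layer is visible even under no
  confounding (sd(w) ≈ 0.11 at n = 5,000 with the default covariate set).
* Visit times enter as confounders, but informative observation times
  (visits triggered by poor response) are not modelled by the generator,
  so the pipeline's robustness to them is untested here.
* The bootstrap re-estimates weights per replicate but conditions on the
  realized cohort composition; very small cohorts (n in the low hundreds)
  will see undercoverage typical of bootstrap MSMs.
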