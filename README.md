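# pdcmsm

Statin adherence from primary-care prescription logs, LDL-cholesterol
response trajectories, and longitudinal causal estimation of the effect of
sustained adherence on LDL-c reduction.

## The problem

Whether a patient keeps taking a prescribed statin is not directly observed
in routine electronic health records, but their refill stream is. The
standard adherence measure is the **proportion of days covered**,

```
PDC = 100 * (tablets prescribed in the study window) / (window length in days)
```

computed over the first year of treatment (PDC1, with special rules for the
prescription that straddles the year boundary) or over the windows between
successive LDL-c measurements (interval PDC_k). Values above 100% occur with
multi-tablet regimens and early refills and are kept up to 200%; higher
values are treated as data errors.

Estimating the *causal* effect of sustained adherence on LDL-c reduction is
complicated by time-varying confounding with feedback: a patient's past
LDL-c response influences their future adherence, and past adherence
influences future response. Ordinary regression adjusting for past response
is biased in this setting (post-treatment bias). The package implements the
standard remedy — a **marginal structural model** fitted by
inverse-probability-of-treatment weighting:

1. **Stage 1.** For each time point `k`, model the continuous exposure
   `PDC_k` given fixed confounders (age at first prescription, sex, baseline
   LDL-c, education, centre), the visit time and the lagged exposure/outcome;
   form stabilized weights from Gaussian density ratios; then exponentially
   tilt the weights so the weighted covariance between every exposure and
   every confounder is exactly zero in sample (a covariate-balancing
   construction for continuous treatments). Balance is verified with weighted
   Pearson and Spearman correlations against the conventional 0.1 cutoff.
2. **Stage 2.** For each `k`, fit weighted least squares of the fractional
   LDL-c reduction `LR_k = (LDL_k - LDL_0) / LDL_0` on `PDC_1 .. PDC_k`
   simultaneously; covariates that fail the balance test are forced into the
   regression. Confidence intervals come from a patient-level bootstrap with
   the weights re-estimated inside every replicate.

From the fitted model one obtains intervention contrasts: the expected extra
LDL-c reduction under sustained full adherence (all PDCs at 100 versus all
at 0) and under each patient holding their own best observed adherence level
(`personal_max_contrast`).

Because real primary-care linkage data of this kind is access-controlled,
the package ships a **synthetic cohort generator** (`sim_config`,
`generate_cohort`) whose linear-Gaussian structural equations encode exactly
the feedback/confounding structure above with known coefficients, and which
renders the latent adherence as realistic refill streams, dated LDL-c
measures, covariate and clinical-event tables. Every stage of the pipeline
is validated by parameter recovery against this ground truth.

## Worked example

```r
library(pdcmsm)

cfg    <- sim_config(n_patients = 2000, seed = 7)
bundle <- generate_cohort(cfg)          # raw-style tables + ground truth
dat    <- assemble_msm_data(bundle)     # trajectories + interval PDCs
des    <- msm_design(dat)
w      <- estimate_weights(des)         # stabilized + balance-calibrated
check_balance(w, des)
est    <- fit_weighted_msm(des, w, n_boot = 200, seed = 1)
est
```

```
Balance report (cutoff 0.1 ): 18 of 18 covariates balanced
Marginal structural model, K = 3  n = 1986  weights: parametric_cbps
Coefficients (LR units per PDC percentage point):
          pdc_1      pdc_2     pdc_3
lr_1 -0.0014390         NA        NA
lr_2 -0.0008234 -7.228e-04        NA
lr_3 -0.0003286 -8.828e-05 -0.001469
Bootstrap: 200 replicates ( 0 dropped )
```

Every covariate is balanced below the 0.1 correlation cutoff after
weighting, and the coefficient of `pdc_3` on `lr_3` (-0.00147) means each
additional percentage point of recent adherence lowers LDL-c by about 0.15%
of baseline; the most recent adherence period has the largest effect. The
generating truth for this configuration is `true_msm_coef(cfg)` (diagonal
-0.0015, -0.0008, -0.0012), so the weighted fit recovers the direct effects
within sampling error, while an unweighted fit is badly biased on the
early-adherence pathway (see the test suite).

```r
ic <- intervention_contrast(est, rep(100, 3), rep(0, 3))
pm <- personal_max_contrast(est, dat[, paste0("pdc_", 1:3)])
```

```
full-adherence contrast: -18.9% (95% CI -23.7 to -14.0)
personal-maximum contrast: -2.8%
```

Sustained full adherence in this synthetic population yields an ~19%
greater LDL-c reduction than no adherence; merely holding one's personal
best level yields ~3%.

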