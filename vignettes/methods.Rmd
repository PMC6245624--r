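---
title: "Vital status under loss to follow-up: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vital status under loss to follow-up: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfmice)
```

## The problem

Treatment programs are judged by how many patients are alive and retained
in care, yet after a decade of follow-up a substantial fraction of any
cohort is "lost to follow-up": no documented death, no documented transfer,
no recent clinic or pharmacy contact. Those patients are not a fifth
outcome category — they are patients whose vital status is *missing*, a
mixture of undocumented deaths, silent transfers and disengagement. How an
analysis treats them decides both the survival estimate and the odds
ratios of every mortality model fitted on the cohort.

`ltfmice` implements the four standard responses over one cohort schema —
complete-case deletion, Kaplan–Meier censoring at the last visit,
tracing-based inverse-probability-of-complete-case weighting, and chained
multiple imputation of outcome and covariates together (plus
imputation-then-deletion as a sensitivity analysis) — and a cohort
generator with known ground truth to test them against.

## The synthetic cohort: what it emulates

`generator_config()` encodes a ten-year adult HIV treatment cohort of 910
patients. Where a published marginal exists for this kind of cohort we use
it; where only medians/IQRs are reported, the distributional family is the
package's choice; where nothing is reported, we choose what we consider a
realistic value once and keep it fixed:

| quantity | default | basis |
|---|---|---|
| n | 910 | cohort size emulated |
| female | 55% | typical of adult ART cohorts in the region |
| age | normal(37, 10), truncated ≥ 13 y | adult cohort, enrolment from age 13 |
| severe poverty (<$1/day) | 40% | package choice |
| Port-au-Prince residence | 60% | package choice |
| weight | normal within sex, medians 56 kg (men) / 49 kg (women), SD 9 | reported medians; normal family is our choice |
| CD4 | lognormal, median 131 cells/µL, σ_log = 1.0, truncated ≤ 1500 | reported median/IQR/range; lognormal is our choice |
| advanced WHO stage | 45% | single binary indicator (see below) |
| baseline TB | 15% | package choice |
| 10-y mortality | ≈ 30% marginal | outcome model, see below |
| pre-tracing LTF | ≈ 17% (156/910) | so that ~29% tracing success leaves ~12% unresolved |
| transfers | ≈ 8%, only among the truly alive | transfers are assumed alive at 10 years |
| missing weight / CD4 | 3% / 12%, completely at random | reported baseline missingness |

The true outcome is drawn from a logistic model on the reporting scale
(age/10, weight/10, CD4/100) whose default coefficients equal the
multivariable odds ratios the package's recovery experiments try to
re-estimate (e.g. OR 1.80 for severe poverty, 0.66 per 10 kg of weight).
The two intercepts (outcome and loss models) were calibrated once by
Monte-Carlo at n = 2×10⁵ so the marginals above hold, and then frozen:
−0.138 (outcome) and −0.653 (loss); the transfer probability 0.135 is
conditional on being alive and not lost.

Loss to follow-up follows its own logistic model on covariates — sicker
patients (lower CD4, lower weight, advanced stage, poverty) are somewhat
more likely to be lost — which makes the mechanism **MAR given
covariates**: exactly the assumption chained imputation relies on. A
single coefficient on the *true* outcome (`ltf_model["true_dead10"]`,
default 0) switches the mechanism to MNAR for robustness experiments; the
package's bias tests show MICE's bias growing monotonically in that
coefficient.

Choices the data cannot arbitrate, decided once here:

* **WHO stage** is one binary "advanced" indicator rather than an ordinal
  four-level score, because mortality models of this kind report a single
  stage OR. The generator parameter is configurable but the analysis
  schema is binary.
* **Loss times**: no distribution of when patients disengage is reported;
  LTF patients get a last visit uniform over their time under follow-up
  (truncated at the death time for those who secretly died).
* **Death times** are front-loaded (Beta(0.8, 1.4) scaled to 10 years)
  because mortality on treatment is highest in the first years. Only the
  Kaplan–Meier method sees these times.
* **Transfers** are sampled only among the truly alive and coded alive at
  10 years in every method — the documented-transfer convention made
  operational. Their censoring time is set to 10, not the transfer date.

What the generator does **not** emulate: visit-level longitudinal records,
regimen changes, time-varying covariates, re-engagement after loss,
measurement error in baseline covariates, or informative transfer. Passing
recovery tests on these cohorts therefore shows the estimators are
implemented correctly and behave as theory predicts under MAR/MNAR loss —
not that any real cohort satisfies those mechanisms.

## Tracing and the inverse-probability weights

Tracing attempts every lost patient and finds each with probability 0.29
(configurable; optionally increasing with recency of the last visit on the
log-odds scale, default slope 0 so the marginal stays interpretable).
Found patients report their true status and are folded into the documented
counts before any analysis, so "LTF" downstream always means
*never found*.

`estimate_ltf_deaths()` scales the death fraction among the found to all
LTF, rounding half-up to a whole count. `stratum_ipw_weights()` then forms
the completeness probability per outcome stratum; its alive-stratum
denominator is documented-alive plus estimated-alive-among-all-LTF (and
symmetrically for deaths), which is the standard worked arithmetic for
this design. Note the symmetric treatment of the dead stratum is an
assumption: the classic presentation prints only the known-alive weight.

Two weighting modes are exposed, and they answer different questions:

* **Outcome-stratum weights** (default): one weight per dead/alive
  stratum. These calibrate the weighted death *count* to the
  known-plus-estimated total — the weighted survival estimate is the
  point — but, because the weight depends on the outcome only, they shift
  the logistic intercept and leave odds ratios at their complete-case
  values.
* **Covariate-conditional weights** (`weights_type = "covariate"`): a
  logistic completeness model of P(documented | covariates, outcome) over
  documented plus traced patients, traced records weighted 1/f. The
  covariates interact with the outcome — completeness may differ by
  covariate within an outcome stratum, which is what lets weighting move
  the odds ratios (the worked example's dead-men weight of 4 with all
  other weights 1 is reproduced exactly by this route).

Weighted fits use a robust (HC0 sandwich) covariance; model-based standard
errors are anti-conservative under weighting. Separation toward
completeness ≈ 1 is harmless (weight → 1) and tolerated; separation toward
0 would explode a weight and raises an error.

## The chained-equation engine

Three variables can be missing: baseline weight (~3%), baseline CD4
(~12%) and the ten-year vital status (~12% after tracing). Each stream of
`chained_imputation()`:

1. initialises every missing cell by a draw from the variable's observed
   values;
2. cycles the variables in a fixed visit order — weight, CD4, vital
   status, i.e. ascending missingness with the covariate before the
   outcome at equal rates — for `n_cycles` iterations;
3. after each update recomputes the *passive* polynomial terms (weight²,
   CD4³ on the reporting scale) so derived terms never drift from their
   raw variable. Each variable's own transforms are excluded from its
   conditional model; the partner variable's transforms are included.

Continuous variables use **predictive mean matching**: a linear model on
the donors, coefficients perturbed by a normal draw scaled by their
estimated covariance, predictions compared with donor predictions from the
posterior-mean fit, and the observed value of one of the k = 5 nearest
donors copied (uniformly at random; distance ties broken by donor index
after a seeded shuffle). Imputed values are therefore always members of
the observed donor pool — no negative CD4s, no extrapolated weights. The
binary outcome uses a logistic fit with a posterior coefficient draw and a
Bernoulli sample per missing row.

Parameter defaults and why:

* **M = 20** imputations — current guidance for this missingness level;
  between-imputation variance is estimated stably and the pooling loss
  factor (1 + 1/M) is negligible.
* **k = 5** PMM donors — the conventional pool: small enough to stay
  local, large enough to avoid repeatedly copying one donor.
* **n_cycles = 10** burn-in per stream — chained-equation software
  defaults differ (some use far fewer); 10 is comfortably past where the
  package's trace diagnostics flatten for this data shape, and it is
  configurable.
* **Posterior draws** are normal approximations around the MLE with the
  estimated covariance — not a full Bayesian sampler; this is the standard
  semi-Bayesian chained-equations shortcut.
* The **cubic "shape" for CD4** is implemented as the term pair
  (CD4, CD4³) and the squared shape for weight as (weight, weight²) — a
  single-power family, not a full fractional-polynomial basis, since the
  selected powers are taken as given.

Degenerate inputs: a variable ≥50% missing is refused, >30% draws a
warning; a single-class observed outcome, separation, or a singular
information matrix raise errors rather than imputing garbage; donor pools
smaller than k shrink k with a warning; covariance matrices are nudged by
1e−10 on the diagonal before the Cholesky draw. Rank-deficient designs
(e.g. a constant covariate in a small cohort) are pruned by pivoted QR
before fitting.

Reproducibility: the engine derives one sub-seed per stream from the spec
seed; identical (data, spec, seed) gives bit-identical imputation sets,
and observed cells are never touched, so they are bit-identical across the
M datasets.

Diagnostics (`imputation_diagnostics()`, `autoplot()`,
`plot_imputed_density()`) are numeric analogues of the usual visual
checks: imputed-vs-observed medians and IQRs, the imputed-outcome death
proportion, per-iteration chain means/SDs, and a no-trend statistic — the
slope of chain mean on iteration with its p-value — standing in for "no
discernible pattern" in a trace plot.

## Estimation and pooling

`logistic_fit()` is IRLS maximum likelihood (convergence tightened to
1e−12 so fits agree with closed-form oracles to 1e−8), dropping and
counting rows with missing model variables — the complete-case behaviour —
and switching to the sandwich covariance under weights. Odds ratios are
reported per 10-year age, 10-kg weight and 100-cell CD4 differences;
`scale_covariates()` attaches those columns once and refuses to run twice.

`rubin_pool()` combines M fits: `q̄`, `W`, `B`, `T = W + (1 + 1/M)B`,
Barnard–Rubin degrees of freedom when the complete-data df are supplied,
and t-based Wald intervals on the log-odds scale. `km_survival()` wraps
the product-limit estimator with Greenwood variance; the test suite checks
it against an independent risk-set enumeration oracle on every event
configuration up to n = 8, with deaths processed before same-time
censorings.

Per-method ten-year survival: Kaplan–Meier reads S(10) off the curve
(computed on the *pre-tracing* cohort, since traced deaths carry no death
time); complete case uses the alive proportion among the outcome-known;
IPW the weighted alive proportion with a robust interval; MICE the
Rubin-pooled alive proportion across the M datasets. With no missing data
all of them coincide exactly, which the tests assert.

Model-size bookkeeping is asserted throughout: univariable complete-case
N varies by predictor, the adjusted model is smallest, IPW excludes the
never-found, MICE always reports the full cohort, and
imputation-then-deletion reports exactly the outcome-observed count (910 −
111 = 799 on the study-shaped cohort). MI-then-delete exists because
imputing the outcome adds between-imputation noise that deleting those
rows removes; on these cohorts its intervals are usually slightly
narrower than full MICE's.

## Problem sizes used in the checks

The validation experiments are sized for a single CPU: the pooled-interval
coverage run uses 50 replicate cohorts at the study scale (n = 910,
M = 20, 10 cycles) and requires ≥90% coverage of the generating
multivariable coefficients; the ground-truth recovery sweep uses 40
replicates at n = 2,500; IPW consistency is checked once at n = 10,000
under full tracing (within 2 points of truth); the MNAR bias ranking uses
a three-point grid at n = 1,500 with M = 4. The CC-versus-MICE bias
comparison runs 8 study-scale replicates and allows a 0.02 log-odds margin
because under MAR-given-covariates both estimators are consistent and
their finite-sample ordering is a coin flip — the strict ordering only
emerges under outcome-dependent loss, which is tested directly via the
survival ordering (KM above MICE/IPW, all above-truth bias concentrated in
KM).

## Known limitations

* The imputation engine handles exactly this schema (two PMM covariates,
  one binary outcome); it is not a general-purpose chained-equations
  framework.
* No time-to-event imputation: MICE addresses the 10-year status, not the
  survival curve's shape; no Cox models, no inverse-probability-of-
  censoring weighting over time.
* Stratum IPW inherits the worked arithmetic's convention of estimating
  deaths among *all* LTF while folding traced patients into the documented
  counts; when tracing succeeds for everyone this double-counts no one,
  and at realistic success rates it reproduces the standard printed
  quantities, but it is a convention, not an identity.
* MAR is untestable in real data; the generator's MNAR switch quantifies
  sensitivity, nothing more.
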