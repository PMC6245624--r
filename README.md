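# ltfmice

Estimating ten-year vital status — and predictors of death — in treatment
cohorts where a sizeable fraction of patients are **lost to follow-up
(LTF)**. LTF is not an outcome: it is a mixed bag of undocumented deaths,
silent transfers and disengagement from care, i.e. *missing data on vital
status*. `ltfmice` implements, over one tabular cohort schema, the analytic
strategies used to handle it and the machinery to compare them against
known ground truth:

* **Complete-case (CC) analysis** — drop every record with a missing
  outcome or covariate;
* **Kaplan–Meier survival** — censor LTF patients at their last clinic
  visit (valid only if loss is unrelated to mortality);
* **Tracing-based inverse probability weighting (IPW)** — actively trace
  lost patients, estimate deaths among all LTF from those found, and weight
  each complete case by the inverse of its probability of being a complete
  case;
* **Multiple imputation by chained equations (MICE)** — impute missing
  vital status *and* missing baseline covariates simultaneously, pool by
  Rubin's rules; plus the **MI-then-delete** sensitivity analysis that
  removes rows with an imputed outcome after imputation.

Because real cohort records of this kind are not publicly deposited, the
package ships a seeded synthetic-cohort generator that emulates a
910-patient HIV treatment cohort (≈30% ten-year mortality, ≈17% lost before
tracing, 8% documented transfers, 3%/12% missing baseline weight/CD4) with
configurable MAR or MNAR loss, so every estimator can be validated by
parameter recovery.

## The statistics in brief

With outcome stratum counts augmented by tracing, the probability that a
patient in stratum *s* (dead/alive) is a complete case is

    p_complete(s) = n_documented(s) / (n_documented(s) + n_estimated(s)),

and each complete case receives weight `1 / p_complete(s)`; deaths among
all `n_LTF` lost patients are estimated as `n_LTF × d/f`, where `d/f` is
the death fraction among those found. When only a fraction `f` of the lost
are traced, each traced case enters the completeness model with weight
`1/f`.

The imputation engine cycles conditional models (predictive mean matching
with k = 5 donors for weight and CD4; a posterior-draw logistic model for
the binary vital status) with passive recomputation of the polynomial
terms weight² and CD4³ used by the outcome models. M = 20 completed
datasets are pooled by Rubin's rules: pooled estimate `q̄`, total variance
`T = W + (1 + 1/M)B` with within-variance `W` and between-variance `B`, and
Barnard–Rubin degrees of freedom. Odds ratios are reported per 10-year age
difference, per 10-kg weight difference and per 100-cell CD4 difference.

## Worked example

```r
library(ltfmice)

cfg      <- generator_config(seed = 2024)          # 910 patients
truth    <- generate_cohort(cfg)                   # ground truth
observed <- apply_missingness(truth, cfg)          # the analyst's view
tracing  <- simulate_tracing(observed, truth, cfg) # find ~29% of the lost

estimate_ltf_deaths(tracing)
#>   n_ltf death_fraction estimated_deaths estimated_alive
#> 1   178          0.232               41             137

report <- compare_methods(observed, tracing,
                          imputation_spec(M = 20, n_cycles = 10, seed = 7))
report
#> Ten-year survival:
#>   method           estimate conf.low conf.high     n
#> 1 km                  0.713    0.682     0.745   910
#> 2 cc                  0.689    0.657     0.721   788
#> 3 ipw                 0.704    0.672     0.734   788
#> 4 mice                0.686    0.654     0.719   910
#> 5 mice_then_delete    0.689    0.657     0.721   788
```

For this seed the cohort's true ten-year survival is 0.686. MICE, which
uses all 910 observations, lands on it exactly; Kaplan–Meier — which
censors the lost and therefore assumes they die like everyone else —
overestimates survival (0.713). The multivariable odds-ratio table
(`report$multivariable`, or `tidy(report)`) shows each method's estimate
per predictor; `autoplot(report)` draws the forest plot, and
`autoplot(imp)` / `plot_imputed_density(imp, observed, "cd4")` provide the
chained-equation convergence diagnostics.

A thin command-line wrapper with `simulate` / `trace` / `impute` / `ipw` /
`compare` subcommands is installed at `inst/cli/ltfmice`.

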