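# vancoforecast

Forecasting next-occasion vancomycin concentrations for therapeutic drug
monitoring (TDM) in critically ill children, and measuring which estimation
strategy forecasts best with the fewest blood samples.

## The problem

Pediatric ICU patients on vancomycin are monitored against an exposure
target (AUC24 400–600 mg·h/L). At each TDM occasion one to three
concentrations are drawn; the clinically useful question is how accurately
the *next* occasion's concentrations can be forecast from the *preceding*
occasion's measurements. This package implements the full comparison as a
reproducible simulation study over virtual pediatric cohorts:

* a one-compartment intermittent-infusion concentration engine with a
  config-driven pediatric population prior (typical-value structure of the
  Le et al. 2014 model; all variances configurable);
* the first-order **Sawchuk–Zaske** two-point method
  (`ke = ln(c1/c2)/(t2 − t1)`, clearance from the steady-state accumulation
  formula);
* **MAP Bayesian estimation** minimizing, over log-scale random effects
  `η`,

  ```
  OBJ(η) = w_data · Σ_j (C_obs,j − f(η, t_j))² / σ_j²
         + w_prior · Σ_k η_k² / ω_k²
  ```

  with `(w_data, w_prior)` = (1, 1) **conventional**, (1, `flat_coef`)
  **flattened** (a small coefficient trusts the data more), and
  (w, 1 − w) **weighted-flattened**, where the data weight `w` is chosen
  per patient and occasion by a pluggable selector (a transparent
  retrospective selector ships in place of the proprietary learned one);
* a seeded **virtual cohort generator** (demographics moment-matched to
  published median/IQR summaries, 60 mg/kg/day q6h protocol, AUC-targeted
  titration, between-occasion clearance walk with drift);
* evaluation by symmetric relative bias and RMSE,

  ```
  d_i   = 100 · (C_forecast,i − C_observed,i) / ((C_forecast,i + C_observed,i)/2)   (%)
  rBias = mean(d_i)          rRMSE = sqrt(mean(d_i²))
  ```

  (both bounded by ±200%), patient-level (cluster) bootstrap confidence
  intervals, and linear mixed-effects factor analysis with a univariable →
  multivariable screen.

## Worked example

Simulate a 20-patient cohort, forecast every subsequent occasion with four
methods using trough-only and peak+trough evidence, and summarise:

```r
library(vancoforecast)

prior  <- default_prior()
cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 7), prior)

methods <- method_set(first_order = TRUE, flat_coefs = 0.125,
                      weighted = weight_retrospective())
pairs <- forecast_table(cohort$patients, prior, methods,
                        selections = c("trough", "peak+trough"))

evaluate_forecasts(pairs, by = "method", n_boot = 500, seed = 1)
```

```
        method   n n_patients rbias rbias_lo rbias_hi rrmse rrmse_lo rrmse_hi
1 conventional 360         20 -19.5    -28.8   -10.43  42.8     37.5     48.0
2  first_order 165         20 -12.4    -22.0    -2.93  42.5     38.2     47.5
3   flat_0.125 360         20 -14.3    -22.6    -5.00  41.2     36.3     45.9
4     weighted 360         20 -15.7    -24.0    -6.99  41.9     37.1     46.7
```

Reading the table: every method under-predicts on average (negative rBias)
because the simulated patients' clearance drifts downward during therapy,
so concentrations rise between occasions; conventional MAP is the most
biased because it also shrinks each patient toward a population prior whose
typical clearance is deliberately 20% too high for this cohort; flattening
the prior (or weighting the data) recovers part of that bias; precision
(rRMSE ≈ 40%) is similar across methods, dominated by between-occasion
variability and residual error. `n` counts forecast–observation pairs; the
`*_lo/_hi` columns are 95% cluster-bootstrap bounds.

The full-size analysis lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R     # 110-patient cohort -> results/cohort_*.csv
Rscript analysis/02_forecast.R     # all methods x selections -> results/forecast_pairs.csv
Rscript analysis/03_evaluate.R     # metrics + LME tables -> results/*.csv
Rscript analysis/04_figures.R      # forest + lead-time figures -> results/figures/
```

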