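---
title: "Forecasting vancomycin concentrations in critically ill children: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting vancomycin concentrations in critically ill children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vancomycin in pediatric intensive care is dosed against a narrow exposure
target (AUC~24~ of 400-600 mg·h/L) in patients whose pharmacokinetics change
quickly. Therapeutic drug monitoring (TDM) supplies one to three measured
concentrations per dosing occasion; the clinical question this package
addresses is how well the *next* occasion's concentrations can be forecast
from the *preceding* occasion's measurements, and which estimation strategy
does it best with the fewest blood draws.

`vancoforecast` implements the complete comparison as a simulation study:
a one-compartment concentration engine with a configurable pediatric
population prior; the first-order (Sawchuk-Zaske) two-point method; maximum
a posteriori (MAP) Bayesian estimation under conventional, flattened-prior
and weighted-flattened objectives; a seeded generator of virtual cohorts;
and an evaluation layer (symmetric relative bias and RMSE, cluster
bootstrap, linear mixed-effects factor analysis).

## The structural model

Concentrations follow a one-compartment model with intermittent zero-order
intravenous infusion and first-order elimination. For a dose of amount $D$
infused over $T$ hours starting at $s$, with clearance $CL$ and volume $V$
(elimination rate $k_e = CL/V$, infusion rate $R = D/T$):

$$
C(t) =
\begin{cases}
0 & t \le s\\[2pt]
\dfrac{R}{CL}\left(1 - e^{-k_e (t-s)}\right) & s < t \le s+T\\[6pt]
\dfrac{R}{CL}\left(1 - e^{-k_e T}\right) e^{-k_e (t-s-T)} & t > s+T
\end{cases}
$$

and a schedule's concentration is the superposition (sum) over its doses —
the model is linear in dose. `infusion_concentration()` evaluates this
closed form; the test suite verifies it against an independent
adaptive-step ODE integration to 10^-6^ relative error. At steady state the
daily exposure is $AUC_{24} = \text{daily dose}/CL$, which the titration
logic uses directly.

## The population prior

Typical values are covariate functions configured as plain R expressions
over `age_mo`/`age_days`, `wt` and `scr` (see
`inst/extdata/prior_pediatric_default.yaml`). The shipped default uses the
typical-value structure of the Le et al. (2014) pediatric vancomycin
population model,

$$
CL_{pop} = 0.248\,\mathrm{WT}^{0.75}(0.48/\mathrm{Scr})^{0.361}
\left(\ln(\mathrm{age_{days}})/7.8\right)^{0.995} \quad (\mathrm{L/h}),
\qquad V_{pop} = 0.636\,\mathrm{WT} \quad (\mathrm{L}),
$$

with between-subject variability log-normal: $CL = CL_{pop} e^{\eta_{CL}}$,
$\eta_k \sim N(0, \omega_k^2)$. The shipped variance and residual-error
magnitudes ($\omega^2_{CL} = 0.09$, $\omega^2_V = 0.04$, proportional
residual CV 20%) are representative pediatric values chosen for this
package — the config header flags them as assumptions, and every one is a
parameter, not a constant. For a median patient of this cohort (10 kg,
Scr 0.34 mg/dL, age 2 years) the prior gives $CL \approx 1.34$ L/h and
$V \approx 6.4$ L, so the empirical 60 mg/kg/day protocol lands the typical
patient at $AUC_{24} \approx 450$ mg·h/L — inside the target window, as a
sensible starting nomogram should.

Creatinine is stored as a right-continuous step series; typical values are
re-evaluated at each prediction time, so a creatinine update during the
forecast lead time propagates into Bayesian forecasts while the estimated
random effects are held fixed. Dose changes enter exactly, through the
actual schedule.

## Estimation methods

**First-order (Sawchuk-Zaske).** From two post-infusion levels of one
interval, $k_e = \ln(c_1/c_2)/(t_2-t_1)$; the peak is back-extrapolated to
the end of infusion ($C_{max} = c_1 e^{k_e(t_1-t_{end})}$; a switch keeps
the measured peak instead), and steady-state clearance follows from the
intermittent-infusion accumulation formula. The method assumes steady
state; fits earlier than five estimated half-lives after the first dose are
flagged with a warning rather than refused, mirroring protocol reality
(sampling starts no earlier than 24 h into therapy).

**MAP estimation.** The objective is penalized least squares over the
log-scale random effects $\eta = (\eta_{CL}, \eta_V)$:

$$
\mathrm{OBJ}(\eta) \;=\; w_{data} \sum_{j=1}^{m}
\frac{\left(C_{obs,j} - f(\eta, t_j)\right)^2}{\sigma_j^2}
\;+\; w_{prior} \sum_{k}
\frac{\eta_k^2}{\omega_k^2},
$$

with $(w_{data}, w_{prior})$ equal to $(1, 1)$ for the conventional
variant, $(1, \texttt{flat\_coef})$ for the flattened variant (a small
coefficient down-weights the prior), and $(w, 1-w)$ for the
weighted-flattened variant. The two flattening parameterizations are
positive multiples of each other at $w = 1/(1+f)$, so they share their
minimizer — an identity the tests check to 10^-12^ and exploit throughout.
$w = 0$ is rejected at validation: the data term would vanish and the
"optimum" would be trivially the population prediction.

The penalty is computed in $\eta$-space, the standard convention for
log-normal between-subject models; a config switch (`penalty_space:
theta`) reproduces the literal additive natural-scale form, with
$\omega$ read as a CV, for users who want the textbook expression.

Optimization is bounded quasi-Newton (L-BFGS-B) over $\eta \in [-6, 6]^2$
from five starts (the population value and ±1 prior SD per axis), with a
tight finite-difference step (10^-6^) so flat optima are located precisely;
ties go to the smallest $\lVert\eta\rVert$ (maximal shrinkage — the
conservative MAP convention). Convergence failure from every start is
flagged on the returned fit, never silent. Inside the objective the model
prediction is floored at 10^-6^ mg/L in the variance model so a
proportional-only residual error cannot produce a zero variance at extreme
trial values. A dense grid search over $\eta$ serves as the oracle in the
test suite (agreement to 10^-3^).

**Weight selection.** The production systems that motivated the weighted
variant choose $w$ per patient and occasion with a proprietary learned
model; that model is deliberately *not* reimplemented. `select_weight()` is
a strategy interface with two transparent implementations: a fixed weight
(default 0.5, which reproduces the conventional fit exactly), and a
retrospective selector that scores each candidate weight by how well a
weighted fit on occasion $i-2$ would have forecast occasion $i-1$, choosing
the best (ties go to the smallest weight, i.e. toward the conventional
balance). Candidates are $w = 1/(1+f)$ over the flattening grid
$\{0.005, 0.02, 0.125, 0.2, 0.3, 0.5, 0.6, 0.8, 1\}$. With fewer than two
prior occasions the selector falls back to the fixed weight — forecasts
from the first occasion cannot use retrospection. The weight is selected
once per (patient, target occasion) and shared across sample selections.

## The virtual cohort

`generate_cohort()` draws cohorts that mirror the published summary of a
110-patient critically-ill pediatric population:

* **Demographics** — age, weight and creatinine are log-normal,
  moment-matched on the log scale to the published medians and IQRs
  (log-median = ln median; log-SD = IQR width / 1.349); age is truncated to
  the 3-month-18-year inclusion range and all draws to the prior's
  covariate support. Correlation between age and weight is not modeled —
  the estimation methods never exploit it, so it would add realism without
  touching any conclusion.
* **Protocol** — 60 mg/kg/day in q6h one-hour infusions; after each
  occasion a Sawchuk-Zaske fit of that occasion's peak and trough titrates
  the daily dose proportionally toward the 400-600 mg·h/L window (clamped
  to 20-100 mg/kg/day).
* **Sampling** — the first occasion starts at least 24 h after the first
  dose; later occasions follow at 1-4 day gaps. Every occasion samples all
  three windows at jittered offsets (peak ~2.0-2.2 h post-dose, i.e. 1-1.2 h
  after the 1-h infusion ends; mid 3.5-4.9 h; trough 0.5-0.6 h before the
  next dose). Sampling all three windows each occasion (12 samples per
  patient at the default 4 occasions) is deliberately denser than the
  clinical cohort's ~5 samples per patient: it populates every
  method-by-selection cell of the design matrix, which the comparison
  needs; it does not change any per-cell estimand.
* **Variability** — between-subject log-normal effects on CL and V
  (from the prior's $\omega^2$), proportional residual error
  (CV 20%), and three mechanisms that make forecasting genuinely hard:
  1. *prior-cohort mismatch* (`cl_shift = 0.8`): the cohort's true median
     clearance sits 20% below the prior's typical value, emulating an ICU
     population the general-pediatric prior describes imperfectly — the
     scenario flattened priors exist for;
  2. *between-occasion variability as a random walk*
     (`iov2_day = 0.02`): log-clearance follows a Gaussian random walk with
     per-day variance 0.02, about 20% CV over a typical 2-day lead.
     A walk, rather than independent per-occasion draws, is what makes
     forecast error *grow with elapsed time*; independent perturbations
     would make the error flat in lead time;
  3. *clearance drift* (`cl_drift_day = -0.02`): a 2%/day mean decline in
     clearance (worsening renal function under critical illness and
     nephrotoxic co-medication), so concentrations drift upward and
     forecasts from past occasions under-predict. This is the accumulation
     mechanism behind both the uniformly negative bias and the
     deterioration of accuracy with lead time. The walk increments are
     half-variance corrected, so the drift parameter is exactly the mean
     clearance trend.

Ground truth (per-occasion clearance, volume, random effects, and
noise-free concentrations) is emitted alongside the ledger for recovery
tests. The generator is byte-reproducible under its seed.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the analysis assumes — not the clinical cohort.
Real data add features the simulator omits: informative sampling (extra
levels drawn when patients destabilize), correlated demographics,
assay-specific error, co-medication effects, and renal trajectories richer
than a drifted random walk. Results on synthetic cohorts therefore support
qualitative orderings (which method is less biased, how error scales with
lead time), never the clinical effect magnitudes.

## Evaluation

Each forecast pair contributes the symmetric relative deviation
$d_i = 100\,(C_{f,i} - C_{o,i}) / \left((C_{f,i}+C_{o,i})/2\right)$;
rBias is the mean and rRMSE the root mean square, both bounded by
±200% / 200% by the symmetric denominator. Confidence intervals come from a
non-parametric bootstrap resampling *patients* (the bootstrap unit is the
cluster, keeping repeated measures together; percentile 2.5/97.5 bounds,
1000 resamples by convention).

The factor analysis fits linear mixed-effects models (random intercept per
patient, maximum likelihood, Wald intervals) with the per-pair signed
deviation as the accuracy outcome and the per-pair absolute deviation as
the precision outcome. The published analysis names its per-observation
outcomes "rBias" and "rRMSE" even though the aggregate formulas define
cohort-level summaries; the per-pair operationalization used here (signed
deviation, absolute deviation) is this package's explicit reading of that
ambiguity. Candidate variables: estimation method (conventional MAP as
reference), sample selection collapsed to one-sample window vs two
concentrations (two-concentration reference), lead time (days), age,
weight, creatinine. Variables significant at p < 0.05 in univariable models
enter the multivariable model.

## Numerical and design notes

* Time is continuous, in hours since the first dose; no rounding anywhere.
* Sampling windows are half-open ([1, 2) h after infusion end for peaks,
  [0.5, 1) h before the next dose for troughs) with peak > trough > mid
  precedence when short intervals make windows overlap; occasions are the
  half-open dosing intervals [start, next start).
* A missing infusion duration defaults to 1 h with a warning — consistent
  with peaks drawn 1-2 h after the end of a 1-h infusion appearing ~2 h
  after the dose.
* Each target occasion is forecast from its immediately preceding occasion
  only; lead time is (first target sample time − last evidence sample
  time)/24 days. Pooling all earlier occasions is a documented alternative
  the design deliberately avoids, to match the preceding-occasion protocol.
* The first-order method uses the first and last observation of the
  preceding occasion when more than two exist (maximal time spread for the
  log-slope).
* Bootstrap intervals are percentile rather than BCa — the simplest
  defensible default at cohort sizes of 50-110 patients; at 50 clusters the
  percentile interval's true coverage for the cohort rBias is ≈94%
  (slightly under nominal), a known small-sample property of the method
  rather than an implementation artifact.
* Default problem sizes — 110 patients × 4 occasions in the acceptance
  script and analysis drivers, 40-110 patients in tests — were chosen so a
  complete run of every method cell stays comfortable on a laptop while
  leaving the qualitative contrasts well resolved.

## Known limitations

One-compartment structure only (no two-compartment distribution phase, no
renal-replacement therapy); no loading-dose logic; no dose-recommendation
output (the pipeline evaluates forecasting, not dosing advice); the learned
weight selector is an interface, not a model; and the clearance-drift and
walk magnitudes are knobs representing plausible ICU dynamics, not
estimates from any cohort.
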