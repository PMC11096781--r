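---
title: "Methods: population pharmacokinetics of daptomycin in critical illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of daptomycin in critical illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daptopk)
```

# The model

Daptomycin disposition in critically ill adults is described by a linear
two-compartment model parameterised as total clearance $CL$ (L/h), central
volume $V_C$ (L), peripheral volume $V_P$ (L) and intercompartmental
clearance $Q$ (L/h), with zero-order (infusion) input into the central
compartment. Writing $k_{10} = CL/V_C$, $k_{12} = Q/V_C$, $k_{21} = Q/V_P$,
the central concentration is a sum of two exponentials with hybrid rate
constants $\alpha > \beta$, the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$. The package evaluates
the during-infusion and post-infusion branches of the closed-form solution
exactly and superposes dose events; the 0.5-h infusion is never
approximated by a bolus, because it materially affects the peak.

Clearance carries the covariate structure of the final published model for
this population:

$$
CL =
\begin{cases}
\theta_{CRRT} & \text{on CRRT}\\[2pt]
\theta_{NR} + \theta_R \cdot \dfrac{CCR}{54} & \text{otherwise,}
\end{cases}
$$

with $CCR$ the Cockcroft–Gault creatinine clearance (mL/min) and 54 mL/min
the cohort median, treated as a fixed constant. CRRT is a structural switch
(two alternative typical-value expressions), not a screened covariate,
mirroring the piecewise form of the final model. Defaults are
$\theta_{NR} = 0.229$, $\theta_R = 0.148$, $\theta_{CRRT} = 0.386$ L/h,
$V_C = 4.14$ L, $V_P = 3.52$ L, $Q = 2.09$ L/h.

The published record of this model is internally inconsistent in places
(the renal slope appears as 0.148 in the model equation but 0.152 in the
estimates table and 0.14 elsewhere; similar small discrepancies affect
$\theta_{CRRT}$, $V_C$, $V_P$, $Q$). The package defaults to the values of
the model *equation* — the headline statement of the model — and treats the
alternatives as within-rounding variants.

Inter-individual variability is lognormal on $CL$, $V_C$ and $V_P$
($P_i = TV_P e^{\eta_P}$, $\eta \sim N(0, \Omega)$), with no IIV on $Q$.
Residual error is combined additive + proportional:
$DV = f\,(1+\varepsilon_p) + \varepsilon_a$, so the residual SD at a
prediction $f$ is $\sqrt{f^2\sigma^2_{p} + \sigma^2_{a}}$. The published
variability entries are interpreted as **variances** (the NONMEM
convention): $\omega^2_{CL} = 0.091$ (about 30% CV) and
$\sigma^2_a = 38.095$ (mg/L)$^2$, i.e. an additive SD of about 6.2 mg/L,
plausible against peaks of 60–90 mg/L. `pop_model(variance_scale = "sd")`
toggles the standard-deviation reading if needed.

# Estimation

`fit_popmodel()` maximises an approximate marginal likelihood of the
FOCE-I/Laplace family. For each subject the conditional objective

$$
g(\eta) = \sum_j \left[ \frac{(y_j - f_j(\eta))^2}{V_j(\eta)} + \log V_j(\eta) \right]
 + \eta^\top \Omega^{-1} \eta + \text{const}
$$

is minimised over $\eta$ by a damped Newton iteration (Gauss–Newton
hessian, step halving, warm starts across outer iterations), with the
residual variance $V_j$ evaluated at the $\eta$-conditional prediction —
the $\eta$–$\varepsilon$ interaction. The subject's $-2\log$ marginal
likelihood is then the Laplace approximation
$g(\hat\eta) - d\log 2\pi + \log\det H$. By default $H$ is a
finite-difference hessian of the exact conditional objective; the cheaper
Fisher/Gauss–Newton form is available (`hessian = "gn"`). On
one-random-effect test problems the default agrees with adaptive
quadrature of the true marginal to well under 0.1, and to ~1e-4 in
near-linear regimes (where the finite-difference hessian step, not the
Laplace approximation, limits precision).

Numerical conventions, fixed and documented:

* The OFV is the **full** $-2\log L$, including all $2\pi$ constants
  (NONMEM's OFV differs by the dataset-constant $n_{obs}\log 2\pi$; AIC/BIC
  *differences* and all likelihood-ratio tests are unaffected).
* Positive parameters (structural thetas, variances, categorical covariate
  factors) are optimised on the log scale inside box bounds
  $[10^{-4}, 10^{3}] \times$ initial; covariate slopes are unbounded on the
  natural scale so that null effects are interior points (keeping
  likelihood-ratio tests calibrated, with no boundary at zero).
* The outer optimiser is `nlminb` with an explicit central-difference
  gradient (step $10^{-5}$), which is far more robust than letting the
  optimiser difference a warm-started objective at machine-epsilon steps.
* Up to three jittered restarts are tried on apparent non-convergence.
* BLQ observations (below 0.05 mg/L) are excluded from the likelihood
  (`MDV = 1`); a censored-likelihood treatment is out of scope.
* `AIC = OFV + 2p`, `BIC = OFV + p log n_{obs}`, with $p$ counting every
  estimated fixed effect and variance parameter ($p = 11$ for the final
  model: 6 thetas, 3 omegas, 2 sigmas — the count that makes the published
  OFV/AIC/BIC triple internally consistent).

Empirical Bayes $\eta$ shrinkage is $100(1 - SD(\hat\eta)/\omega)$.
Standard errors come from a finite-difference hessian of the objective at
the optimum (sandwich estimators are out of scope).

The covariance of the random effects is estimated diagonally; a full
$\Omega$ can be supplied and evaluated (`foce_ofv()`) to explore
off-diagonal elements as a configuration experiment, but off-diagonal
estimation is not part of the fitting pipeline, matching the final
published model, which is diagonal.

## Covariate screening

`stepwise_covariates()` implements greedy forward inclusion / backward
elimination with the conventional $\chi^2_1$ thresholds: accept while
$\Delta OFV > 3.84$ ($\alpha = 0.05$), retain only if removal costs
$\Delta OFV > 6.635$ ($\alpha = 0.01$). The screening functional forms are
open design choices (the published analysis does not report forms for
rejected candidates); the package uses:

* clearance, continuous: additive slope
  $CL = \theta_{base} + \theta_{cov}\,(cov/\text{median})$, matching the
  final model's renal term — applied to the non-CRRT branch only, since
  CRRT clearance is its own regime;
* volumes, continuous:
  $V = \theta_{base}(1 + \theta_{cov}\,(cov-\text{median})/\text{median})$;
* categorical (sex): a multiplicative factor.

Ties in a forward round break by largest $\Delta OFV$, then fewest added
parameters, then declaration order. Candidates whose fits fail are skipped
and logged in the trace. Under a null covariate the forward acceptance
rate is ~5% by construction (the $\chi^2_1$ law of $\Delta OFV$), which
the test suite verifies by simulation.

## Bootstrap

`bootstrap_fit()` resamples subjects with replacement at the original
cohort size and refits each resample, warm-started at the original
estimates; replicate medians and 2.5–97.5 percentile intervals are
reported and non-converged replicates are counted and excluded (with a
warning above 10%).

# The synthetic cohort

`generate_dataset()` emulates the study conditions: 64 subjects (39 on
CRRT, 43 male), age $\sim N(57.5, 16.5^2)$ truncated to 18–95 y, lognormal
weight (median 64.5 kg, truncated to 45–170) and serum creatinine (median
106 µmol/L, truncated to 21.7–845.4), creatinine clearance derived by
Cockcroft–Gault and clamped to 8.3–200.2 mL/min, 500 mg q24h 0.5-h
infusions on days 1–7, and the fixed sampling schedule (day 1: 0, 0.5, 1,
2, 4, 8, 12, 24 h after end of infusion; day 3: pre-dose plus the same
offsets; days 5 and 7: pre-dose, 0.5 and 4 h) — 23 nominal samples per
subject. "After infusion" is read as end-of-infusion: a sample at
infusion *start* would be a pre-dose sample, which the day-3 schedule
lists separately. Observations are thinned by independent Bernoulli
retention 737/1472, so the expected observation count matches the 737
concentrations of the study dataset.

Unreported shape parameters were fixed once by calibration to the printed
summaries: weight `sdlog` 0.18, creatinine `sdlog` 0.75 (giving a
large-sample CCR median within 10% of 54.25 mL/min), BMI/albumin/severity
scores from simple truncated marginals.

What the generator does **not** emulate — and hence what passing recovery
tests cannot show about real data: covariate marginals are independent
(the joint distribution is unreported) except for the deterministic CCR;
missingness is independent thinning rather than a clinical dropout
mechanism; renal function is constant within subject; CRRT circuit
mechanics (filter, flows) are not modelled; the single 170-kg subject is
represented only through the weight distribution's upper truncation. The
generator records its truth (per-subject $\eta$ and individual parameters)
as an attribute for recovery testing.

# Dose simulations

`pta_grid()` simulates 1000 virtual subjects per dose × renal-function
cell (doses 400–700 mg q24h; CCR 20/30/40/60/90/120 mL/min or CRRT),
varying only the random effects, with covariates pinned at the cell's
nominal renal function and no residual error added (exposure is
model-predicted, not measured; `pta_config(residual = TRUE)` exists but is
off by default). Efficacy is $P(\text{AUC}_{24}/\text{MIC} \ge 666)$ at
MIC 1 mg/L; safety summaries report $P(\text{AUC}_{24}/\text{MIC} \ge 1422)$
and $P(C_{min,ss} \ge 24.3 \text{ mg/L})$.

Three AUC$_{24}$ definitions are exposed because published exposure tables
for this model are not reproducible cell-by-cell under any single one (the
printed medians are non-monotonic in CCR, and one renal column duplicates
the CRRT column — the grid appears partly erroneous). The default is the
steady-state definition AUC$_{24}$ = dose/$CL$, exact for linear kinetics;
`day1` and `interval_k` integrate the closed form over the first or the
$k$-th dosing interval. Under the steady-state definition with clearance
variability only, PTA has the closed form
$\Phi\!\left(\log\frac{dose}{666\cdot MIC\cdot TVCL}\,/\,\omega_{CL}\right)$,
which serves as an independent oracle for the Monte Carlo path (agreement
within 3 percentage points at $n = 1000$).

A related documented discrepancy: with the published typical parameters,
the typical steady-state trough on CRRT at 500 mg q24h computes to about
27.7 mg/L, *above* the 24.3 mg/L safety threshold, so claims that most
CRRT patients stay below that trough are not derivable from the typical
values; the package reports the simulated fraction rather than asserting
either way.

# Degenerate inputs and numerical edges

* $\alpha \approx \beta$ (repeated hybrid root): roots are computed
  cancellation-free (large root directly, small root by Vieta) and
  separated by a $10^{-7}$ relative nudge so the partial-fraction
  coefficients stay finite.
* $Q = 0$ collapses to one-compartment kinetics; the public constructor
  flags it, and zero-coefficient exponential terms are skipped rather than
  evaluated as 0/0.
* Small $\lambda t$ uses `expm1`-based series for $(1-e^{-\lambda t})/\lambda$
  and its integral.
* Negative simulated concentrations (possible under the additive error)
  are flagged BLQ, not truncated, preserving the symmetry of the error
  model for estimation tests.
* An all-zero residual variance is allowed for noise-free simulation but
  rejected by the estimator.

# Problem sizes used by the tests and the acceptance script

Chosen as the package's own trade-off between Monte-Carlo precision and
runtime: recovery experiments use the full 64-subject design with medians
over 5 seeds; bootstrap accuracy checks use 200 replicates (the
`bootstrap_fit()` default remains 1000 for analyses); PTA cells use 1000
virtual subjects; the
null-covariate selection-rate simulation uses 200 replicates of a light
30-subject one-compartment design (the $\chi^2_1$ calibration of
$\Delta OFV$ does not depend on the heavier structural model); VPC
calibration uses 20 seeds with 400 simulation replicates each.

# Known limitations

The estimator is a Laplace/FOCE-I-class approximation, not a reimplementation
of any specific commercial implementation; exact numerical equality with
other software is not promised — the contract is quadrature-oracle
agreement and parameter recovery within stated tolerances. SAEM-type
estimators, inter-occasion variability, censored-likelihood BLQ handling,
covariate effects on $Q$, time-varying renal function and
MIC-distribution-weighted response fractions are out of scope.
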