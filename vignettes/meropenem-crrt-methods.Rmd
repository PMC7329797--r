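---
title: "Methods: population pharmacokinetics of meropenem during CRRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of meropenem during CRRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(meroCRRT)
```

This vignette documents the models, numerical choices and design decisions
behind `meroCRRT`, and what the test suite does and does not establish.

## The structural and statistical model

Meropenem disposition in a patient on continuous renal replacement therapy
is described by a linear two-compartment model with a zero-order infusion
into the central compartment and elimination exclusively via the CRRT
circuit:

$$V_1 \frac{dC_1}{dt} = -Q C_1 + Q C_2 - \mathrm{Cl}_{CRRT} C_1 + R(t),
\qquad V_2 \frac{dC_2}{dt} = Q C_1 - Q C_2,$$

with central and peripheral volumes $V_1, V_2$ (l), inter-compartmental
clearance $Q$ (l/h) and CRRT clearance $\mathrm{Cl}_{CRRT}$ (l/h).  The
infusion rate $R(t)$ (mg/h) is nonzero during each infusion; as published
the mass-balance equations omit the input term and it is restored here by
the standard convention, since no dosing can be represented without it.
Renal and non-renal clearance, saturable binding and
ultrafiltrate/sieving-coefficient mechanisms are out of scope; the cohort's
residual diuresis was essentially nil and meropenem protein binding (~2%)
makes free and total plasma concentration interchangeable for target
attainment, so total concentration is used against MIC without a binding
correction.

The production evaluation path is the closed-form bi-exponential solution
(superposition across infusions; geometric-series accumulation for the
periodic steady state), because the Monte Carlo dosing simulations need on
the order of $10^6$ profile evaluations.  Numerical integration of the
system (`deSolve::lsoda`, split at every infusion on/off boundary) serves
as an independent oracle in the tests only.  For strictly positive
parameters the characteristic discriminant
$(k_{10}+k_{12}+k_{21})^2 - 4k_{10}k_{21}
 = (k_{10}-k_{21})^2 + k_{12}^2 + 2k_{12}(k_{10}+k_{21})$
is strictly positive because $k_{12} = Q/V_1 > 0$, so the repeated-root
(equal exponents) degeneracy is unreachable and no limiting branch is
needed; the constructor rejects non-positive parameters outright.

Between-subject variability is log-normal per parameter,
$P_i = \theta_P\, c_i \exp(\eta_P)$ with $\eta_P \sim N(0, \omega_P^2)$,
where $c_i$ is the product of multiplicative covariate-law factors (power,
linear or indicator form; the continuous forms are anchored at the
covariate's study median so that $P_i = \theta_P$ at the reference).  The
reported IIV magnitudes are %CV under the log-normal convention
$\%CV = 100\sqrt{e^{\omega^2}-1}$ (the only reading under which the
published variability table is internally consistent), so e.g. 53.1 %CV on
$V_1$ corresponds to $\omega^2 = \ln(1 + 0.531^2) \approx 0.248$.
Residual error is combined additive + proportional,
$C_{obs} = C_1(1+\varepsilon_{prop}) + \varepsilon_{add}$, with the
proportional SD read as a fraction (24.1 %CV $\to$ 0.241).  Random effects
are uncorrelated (no off-diagonal $\Omega$ is reported) and the $\eta$
ordering is fixed as (V1, CL, Q, V2); a parameter whose $\omega^2$ is
exactly zero (Q in the reference model) carries no $\eta$ at all.

## Estimation

The marginal likelihood is approximated subject-by-subject by a Laplacian
expansion at the conditional mode of $\eta$, with the residual variance
evaluated at the conditional predictions — the "interaction" convention of
first-order conditional estimation.  The reported OFV is $-2\log L$
including all normalizing constants, so nested-model OFV differences are
likelihood-ratio statistics (gates: 3.84 for inclusion at $p<0.05$, 7.9
for retention at $p<0.005$, 1 df).

Numerics, all chosen here:

- **Inner problem** (per subject): Newton iteration with an Armijo line
  search, started at $\eta = 0$, gradient tolerance $10^{-8}$ (infinity
  norm), at most 100 iterations.  Gradients are complex-step derivatives
  (exact to machine precision — the closed-form profile is analytic in the
  parameters); the Newton Hessian is a central difference of those
  gradients.  Non-positive-definite Hessians are Levenberg-regularized.
- **Outer problem**: `stats::nlminb` (PORT quasi-Newton) over
  $\log\theta$, raw covariate coefficients, $\log\omega^2$ and
  $\log\sigma$, relative OFV tolerance $10^{-6}$, bounds keeping all
  variances in $[10^{-6}, 25]$.  During the outer search the inner modes
  warm-start from the previous iterate; the *reported* OFV is then
  recomputed canonically with the inner search started at 0, so OFV values
  are deterministic functions of the estimates and comparable across fits.
- **Convergence bookkeeping**: PORT's "false convergence" code fires
  routinely when a fit starts at (or near) its own optimum — warm-started
  bootstrap refits do exactly that — and is accepted as converged when the
  objective is finite.  A fit with any $\omega^2$ on its lower bound is
  flagged `boundary`; the bootstrap counts boundary or failed fits as
  unsuccessful and summarizes the rest.
- **Stepwise search**: forward inclusion adds the candidate with the
  largest OFV drop $\ge 3.84$ each round; backward elimination removes the
  law whose deletion raises the OFV least, unless that rise exceeds 7.9.
  Ties within $10^{-6}$ break lexicographically by (parameter, covariate,
  form).  A candidate whose fit errors is skipped and logged in the trace.
- **Below-LLOQ handling**: observations with $0 <$ concentration $<$ LLOQ
  (0.1 mg/l) are flagged and excluded from fitting (flag-and-discard);
  nothing more elaborate is described for the original analysis.
  Excluded records (e.g. positive predose samples of drug-naive subjects)
  are retained in the dataset with a flag and reason, never deleted.

**Accuracy of the approximation.**  The Laplacian is checked against
adaptive 1-D quadrature of the exact marginal likelihood on
single-subject toy problems.  In the regime the estimator is designed for
— several observations per subject, moderate IIV ($\omega^2 \lesssim
0.25$) — the two agree to better than 0.1 in OFV.  The error grows with
$\omega^2$ and with data sparsity (it is driven by the skewness of the
integrand), and for $\omega^2 \ge 0.3$ with one or two observations it can
exceed that figure; the implementation itself is verified separately to
match an independent pure-R Laplace evaluation, so the discrepancy is
approximation error inherent to the method, not a defect.  Standard errors
are deliberately not computed from an asymptotic covariance matrix; the
bootstrap provides interval estimates, matching the original analysis.

## The synthetic cohort generator

No raw clinical data are distributed, so estimator validation runs on
synthetic cohorts that emulate the trial design: 19 adult ICU patients on
CRRT, 1 g meropenem infused over 1 h every 8 h, arterial samples just
before and 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 3, 4 and 8 h after the start
of one monitored infusion; 9 of 19 subjects are sampled at their first
dose, the rest at steady state (the generator administers six preceding
doses, i.e. 48 h of therapy — beyond ten terminal half-lives of the
typical patient, $t_{1/2,\beta} \approx 3.5$ h).  Covariates: albumin from
a scaled Beta on 15.6–31.8 g/l calibrated so the median is 24.6 (the
published summary gives only median and range, so a unimodal bounded
distribution is the natural minimal choice); weight uniform on 60–100 kg;
age from a left-skewed scaled Beta on 36–79 years; sepsis status drawn
with probability increasing as albumin falls (mirroring the observed
sepsis–hypoalbuminaemia association), used only as a decoy candidate in
covariate-search tests.  The trial recorded 256 concentrations from 19
patients versus the 209 scheduled here (19 × 11): the surplus reflects
extra clinical sampling that is not part of the stated schedule and is not
emulated.

Three deliberate idealizations: (1) the predose sample of a drug-naive
subject is recorded as a missing value — in reality it is a no-signal
assay report; feeding it to the likelihood as an exact zero would be
degenerate, since model and datum are both identically zero there; (2)
negative concentration draws from the additive error are mapped to a
below-LLOQ sentinel (0.05 mg/l), which the LLOQ filter then discards, the
way an assay would report them; (3) an optional contamination rate plants
spurious positive predose records so the outlier-exclusion rule can be
exercised (expected count = rate × total observations, all placed on
eligible first-dose records).

Passing recovery tests on these cohorts shows the estimator is unbiased
and the selection machinery is calibrated *under the generating model*;
it cannot show robustness to features the generator does not produce —
model misspecification, correlated random effects, occasion-to-occasion
variability, irregular real-world sampling, or the true joint distribution
of the 17 candidate covariates (only albumin and its sepsis link are
modelled with fidelity).

## Dosing simulations

PTA is computed on model-predicted individual concentrations *without*
residual error (assay noise is not pharmacology; standard PK/PD practice),
at steady state over one dosing interval via the closed-form accumulation
formula.  %T>MIC is the measure of $\{t: C(t) > \mathrm{MIC}\}$ over the
interval, with threshold crossings bracketed on a 257-point grid and
refined by root finding to $10^{-6}$ h.  The MIC grid is the exact
two-fold ladder from 0.064 mg/l with the top rung capped at 64 mg/l, and
MIC-at-90%-PTA interpolates linearly in $\log_2$ MIC between grid points.
Note that at the bottom of the ladder the whole-interval target is *not*
automatically met by everyone: the log-normal tails put a small
percentage of simulated subjects' troughs below 0.064 mg/l.

Dose changes act by linearity: scaling the dose by $fr$ shifts the PTA
curve to $\mathrm{PTA}_{fr}(\mathrm{MIC}) =
\mathrm{PTA}_1(\mathrm{MIC}/fr)$, so the dose multiplier needed to hold a
breakpoint at 90% PTA is breakpoint / MIC$_{90}$.  Uncertainty bands
recompute the curve per bootstrap parameter set and summarize pointwise
(median, 5th–95th percentile) using common random numbers — one shared
standard-normal $\eta$ block across sets — so the band isolates parameter
uncertainty and identical sets give an exactly zero-width band.  Defaults:
1000 subjects per curve, seed mandatory in every stochastic entry point.
Percentiles everywhere (VPC, bootstrap, PTA bands) use linear
interpolation of order statistics (`stats::quantile` type 7), stated once
and frozen.

A caveat on reproducing published headline values: a PTA point value
computed at the point estimates differs from the median of PTA over
bootstrap parameter sets whenever the PTA is a nonlinear function of the
parameters; where a published figure plots bootstrap medians, a
point-estimate run can legitimately sit a few percentage points away even
with an exact reimplementation.  The package implements both (point run
by default; `pta_with_uncertainty()` for the bootstrap-median route).

## Model evaluation

The VPC simulates replicate datasets under the original design (same
subjects' covariates, doses and sampling times, residual error included;
negative simulated concentrations retained for generative fidelity), bins
observations at the nominal times-after-dose — the design is fixed, so
quantile binning would only blur it — and overlays observed 5th/50th/95th
percentiles on the 5th–95th percentile band of the same statistic across
simulations.  By construction the observed statistic of a well-specified
model falls inside its band 90% of the time, which is what the
self-coverage test measures.  The bootstrap resamples subjects (not
observations) with replacement to the original cohort size and refits with
warm starts from the original estimates.  Conditional weighted residuals
decorrelate each subject's residual vector by the lower-triangular
Cholesky factor of $G\Omega G' + \mathrm{diag}(v)$, with $G$ the Jacobian
of the prediction in $\eta$ at the conditional mode and $v$ the residual
variances at the conditional predictions, against the linearized
expectation $f(\hat\eta) - G\hat\eta$.

## Problem sizes in the shipped tests

The test suite scales the heavier evaluation experiments to sizes chosen
for tight feedback while keeping the checks statistically meaningful:
parameter recovery uses the median over 5 replicate 50-subject cohorts
(the single-cohort sampling spread of $\omega^2_{V_2}$ spans a multiple of
its value — the original bootstrap interval for it runs from near 0 to 138
%CV — so a single replicate is noise-dominated); the covariate-search
recovery case also runs at 50 subjects, where the 3.84 gate has high power
for the $-2.87$ albumin exponent, while the type-I control runs 20
null-model searches at the trial's own n = 19; the bootstrap check uses
100 resamples (the reference analysis used 1000) and VPC self-coverage
averages 30 replicate designs at 120 simulations each.  The Monte Carlo
dosing simulations run at the study's full 1000 subjects per curve.

## Known limitations

- The estimator is a Laplacian approximation; it is validated against
  quadrature in 1-D and against parameter recovery in the full model, but
  exact NONMEM FOCE-I numerics are not reproduced and small OFV offsets
  relative to other software are expected.
- $\omega^2_{V_2}$ is weakly identified by the 8-h, single-interval
  design; single-cohort estimates scatter widely (in line with the very
  wide published bootstrap interval) and occasionally collapse toward
  zero.
- MIC-at-90%-PTA inherits Monte Carlo noise amplified by the local slope
  of the PTA curve; at 1000 subjects it is reproducible only to roughly a
  tenth of a two-fold dilution step.
- The CLI, JSON and CSV interfaces are thin wrappers; no attempt is made
  to read NONMEM control streams or outputs.
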