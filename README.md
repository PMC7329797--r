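# meroCRRT

Population pharmacokinetics of standard-dose meropenem in critically ill
patients on continuous renal replacement therapy (CRRT), as a tested,
reusable R pipeline.

Meropenem is a time-dependent carbapenem: its bactericidal effect tracks
%T>MIC, the fraction of the dosing interval during which the plasma
concentration stays above the pathogen's minimum inhibitory concentration.
In septic patients on CRRT both the volume of distribution and the
elimination route are altered, so standard dosing (1 g infused over 1 h
every 8 h) may or may not reach the classical 40%T>MIC target — and often
misses the stricter 100%T>MIC target advocated for the critically ill.
This package implements the full analysis workflow for that question:

- **Structural model.** Two-compartment disposition with zero-order
  infusion input and elimination by CRRT clearance only:
  `V1 dC1/dt = −Q·C1 + Q·C2 − Cl_CRRT·C1 + R(t)`,
  `V2 dC2/dt = Q·C1 − Q·C2`, solved in closed (bi-exponential) form with an
  ODE integrator as an independent test oracle.
- **Population model.** Log-normal inter-individual variability
  `P_i = θ_P · exp(η_P)`, combined additive + proportional residual error
  `C_obs = C1(1 + ε_prop) + ε_add`, and multiplicative covariate laws —
  in the bundled reference model an albumin power law on the central
  volume, `V1_i = 27.9 · (ALB_i / 24.6)^−2.87 · exp(η)` (hypoalbuminaemic
  patients distribute the drug into a much larger apparent volume).
- **Estimation.** First-order-conditional-style approximate marginal
  likelihood: a Laplacian expansion at each subject's conditional mode of
  η with the residual variance evaluated at the conditional predictions,
  OFV-based likelihood-ratio model comparison (ΔOFV 3.84 forward / 7.9
  backward), and stepwise covariate selection.
- **Model evaluation.** Visual predictive checks, conditional weighted
  residuals, and a nonparametric subject-resampling bootstrap.
- **Dosing simulation.** Monte Carlo probability of target attainment
  (PTA) over a two-fold MIC ladder (0.064–64 mg/l) and the albumin range,
  with MIC-at-90%-PTA, dose-linearity rescaling (`fr = dose/1000`) and
  bootstrap-based uncertainty bands.
- **Synthetic cohorts.** A generator emulating the study design (19
  subjects, 1 g q8h over 1 h, 11 samples over one interval, albumin
  15.6–31.8 g/l with median 24.6) with known ground truth, used by the
  estimator-validation tests.

## Worked example

Probability of attaining the whole-interval target under standard dosing
for a patient with the cohort's median albumin:

```r
library(meroCRRT)
model   <- meropenem_reference_model()
regimen <- dosing_regimen(dose = 1000, tau = 8, duration = 1)
pta <- simulate_pta(model, regimen, albumin = 24.6, target_fraction = 1,
                    n_subjects = 1000, seed = 20)
print(pta)
#> PTA (100%T>MIC target), 1000 subjects, 1000 mg q8h 1h infusion, albumin 24.6 g/l
#>     mic  pta
#>   0.064 99.5
#>   0.128 99.3
#>   0.256 97.5
#>   0.512 94.4
#>   1.024 86.1
#>   2.048 67.3
#>   4.096 36.6
#>   8.192  8.2
#>  16.384  0.4
#>  32.768  0.0
#>  64.000  0.0
m90 <- mic_at_pta(pta, level = 90)
sprintf("MIC at 90%% PTA: %.2f mg/l", m90$mic)
#> "MIC at 90% PTA: 0.74 mg/l"
sprintf("dose multiplier to cover 2 mg/l: %.1f-fold", 2 / m90$mic)
#> "dose multiplier to cover 2 mg/l: 2.7-fold"
```

Reading: at MIC 2 mg/l only about two-thirds of simulated median-albumin
patients keep their trough above the MIC for the whole interval, the MIC
covered in 90% of patients is ≈0.7 mg/l, and holding the 2 mg/l breakpoint
at 90% PTA would need roughly a 3-fold higher dose (by dose-linearity).

The same workflow is scriptable from a shell via the installed `meropk`
entry point (`simulate-cohort`, `fit`, `covariate-search`, `bootstrap`,
`vpc`, `pta` subcommands); see `?pk_cli`.

Estimation on data (here: a synthetic cohort with known truth):

```r
sim <- generate_cohort(cohort_config(), seed = 1)
fit <- fit_population(sim$dataset,
                      model_spec(covariate_laws = list(
                        covariate_law("V1", "albumin", "power", -1, ref = 24.6))),
                      init = meropenem_reference_model())
fit$model   # estimated thetas, omega^2, sigma
boot <- bootstrap_fit(sim$dataset, fit$spec, n_boot = 100,
                      init = fit$model, seed = 1)
```

## Layout

- `R/`, `src/` — package code (closed-form kinetics, population model,
  compiled FOCE core, diagnostics, PTA, cohort generator, CLI).
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
- `vignettes/meropenem-crrt-methods.Rmd` — the methods vignette: model
  assumptions, estimation numerics, generator design, limitations.
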