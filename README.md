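# msjoint

Joint longitudinal–survival modelling of genetic prognostic indices in
relapse-onset multiple sclerosis (ROMS).

## What this package is for

In ROMS, relapses and stepwise disability worsening (EDSS-based, on the
0–10 half-point scale) are recurring, interdependent processes observed
over 15+ years of follow-up. `msjoint` estimates the *indirect*,
time-dynamic association between the two outcomes by routing it through a
longitudinal **genetic prognostic index** (GPI), in three stages:

1. **Stage 1 — GPI construction.** SNPs predictive of one outcome are
   screened by an elastic-net penalized Cox partial likelihood on
   counting-process transition intervals (subject-grouped cross-validation),
   then fitted in a mixed-effects Cox model (Gaussian subject frailty,
   Breslow ties) with per-SNP main effects, SNP × log-time interactions and
   SNP × standardised-latitude interactions. The GPI at time *t* is the
   genetic linear predictor
   `GPI_i(t) = Σ_j g_ij (β_j + α_j log t + γ_j lat_i)`.
2. **Stage 2 — trajectory model.** A Bayesian mixed model smooths each
   subject's GPI series over natural cubic splines of time (internal knots
   at the 33rd/66th percentile of follow-up, boundary knots 0.5 and 13
   years), giving subject-specific values `m_i(t)` and analytic slopes
   `m_i'(t)`.
3. **Stage 3 — joint model.** The recurrent-event hazard
   `h_i(t) = h0(t) exp{w_i'γ + A_i(t)}` has a penalized P-spline baseline
   and an association term `A_i(t)` under the current-value (CV),
   current-value-and-slope (CVS) or cumulative-effects (CE) hypothesis,
   optionally with GPI × DMT-duration interactions and 3/6-month lagged
   survival times (PIRA-style). Estimation is Metropolis-within-Gibbs MCMC
   with Gelman–Rubin diagnostics and DIC.

Dynamic person-specific predictions `π(u|t)` (event-free probability to
horizon *u* given survival and marker history to *t*) and the
model-comparison metrics AUC(t, Δt) and PE(t, Δt) at t = 2.5/5/7.5, Δt = 2.5
years complete the pipeline. A seeded synthetic-cohort generator
(`simulate_disease_course()`, `simulate_joint_model_data()`) reproduces the
statistical structure the analysis assumes and backs the validation suite.

Posterior means and 95% credible intervals are reported on the log-hazard
scale and, via `to_hazard_ratio()`, on the HR scale rounded to two decimals
— e.g. an association summary of 1.086 (1.068; 1.104) corresponds to
HR 2.96 (2.91; 3.02).

## Worked example

A reduced synthetic run (150 subjects, 15 SNPs, strong true coupling of
both outcomes to the genetic index, short chains):

```r
library(msjoint)
cfg <- run_config(
  simulation   = list(n_subjects = 150, n_snps = 15,
                      truth = list(n_snps = 15, assoc_value = 0.8,
                                   relapse_rate = 0.45, edss_up_rate = 0.45,
                                   seed = 99)),
  directions   = "worsening_to_relapse", associations = "CV",
  mcmc         = mcmc_control(1500, 700, 2, seed = 2),
  traj_mcmc    = mcmc_control(800, 400, 1, seed = 3),
  selection    = list(penalty = 0.02), seed = 1)
run <- run_three_stage(cfg)
print(run)
#> Three-stage joint-model run: 150 subjects, 1800 transitions ( 343 worsening / 177 relapse events )
#>    worsening_to_relapse : fits = CV
print(run$directions$worsening_to_relapse$fits$CV)
#> Bayesian joint model (relapse, CV, CCJM): 2 chain(s), DIC = 1016.3, max R-hat = 1.122
#>         param mean   lo   hi
#> 1 alpha_value 1.62 1.16 2.11
hr <- run$directions$worsening_to_relapse$tables$hazard_ratio
print(hr[, c("effect", "hr")], row.names = FALSE)
#>          effect                hr
#>             sex 1.05 (0.78; 1.44)
#>         log_age 1.29 (0.72; 2.27)
#>             bmi 1.01 (0.97; 1.05)
#>   relapse_count 0.96 (0.85; 1.07)
#>             t2l 0.98 (0.94; 1.04)
#>            vitd 0.95 (0.71; 1.27)
#>  WS-GPI [value] 5.07 (3.19; 8.21)
```

Reading the output: from 1800 visit-to-visit transitions the engine finds
343 confirmed worsening events and 177 confirmed relapses; the
worsening-specific index (WS-GPI) is built from the worsening events and
regressed, as a longitudinal marker, against the relapse hazard. The
association posterior mean 1.62 (CI 1.16–2.11 on the log scale; HR 5.07,
CI 3.19–8.21) correctly detects the positive coupling planted in the
generator, the confounder HRs hover around 1 (none were given true
effects), and the largest split-free R-hat of 1.12 indicates adequate
mixing at this reduced chain length.

Per-subject prediction from a fitted model:

```r
fit <- run$directions$worsening_to_relapse$fits$CV
hist <- subset(run$directions$worsening_to_relapse$trajectory$data,
               subject_id == "S0001" & time <= 5)
conditional_survival(fit, hist, t = 5, u = c(5, 6, 7.5), n_mc = 1000, seed = 1)
```

## Layout

- `R/` — event engine, GPI construction, trajectory model, joint model,
  dynamic prediction, pipeline orchestration, synthetic cohorts.
- `tests/testthat/` — unit, property and acceptance suites (oracle checks
  against brute-force partial likelihoods, dense Riemann sums, closed-form
  survival, hand-enumerated fixtures).
- `vignettes/joint-gpi-models.Rmd` — the methods vignette: model,
  assumptions, priors, numerical choices, generator scope, limitations.
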