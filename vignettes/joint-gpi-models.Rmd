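---
title: "Joint longitudinal-survival modelling of genetic prognostic indices in relapse-onset MS"
author: "msjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint longitudinal-survival modelling of genetic prognostic indices in relapse-onset MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In relapse-onset multiple sclerosis (ROMS), relapses and the stepwise
accumulation of disability (measured by EDSS, the Expanded Disability Status
Scale, a 0--10 scale in 0.5-point steps) are intertwined processes. Whether
relapses drive later disability worsening -- and conversely whether worsening
predicts later relapses -- cannot be read off a single regression, because
both outcomes recur, both evolve over 15 or more years, and both share
genetic and environmental drivers. `msjoint` implements a three-stage
strategy for estimating the *indirect*, time-dynamic association between the
two outcomes, routed through longitudinal **genetic prognostic indices**
(GPIs), together with the machinery to validate the whole pipeline on
synthetic cohorts.

The three stages, run in either direction (worsening-specific index against
relapse hazard, or relapse-specific index against worsening hazard):

1. **GPI construction** (`select_variants()`, `fit_gpi_cox()`). Candidate
   SNPs are screened with an elastic-net penalized Cox partial likelihood on
   counting-process transition data (folds grouped by subject, penalty by
   cross-validated partial-likelihood deviance with a 1-SE rule). The
   retained SNPs -- plus a force-included tag for the primary HLA-DRB1
   signal when available -- enter a mixed-effects Cox model with a Gaussian
   subject frailty, each SNP contributing a main effect, an interaction with
   log time since onset ("alpha"-type time-dynamic effects) and an
   interaction with standardised site latitude ("gamma"-type effects),
   adjusted for log disease duration and latitude. The GPI is the genetic
   part of the linear predictor,
   $\mathrm{GPI}_i(t) = \sum_j g_{ij}\,(\hat\beta_j + \hat\alpha_j \log t + \hat\gamma_j \ell_i)$,
   evaluated at each visit.

2. **Trajectory smoothing** (`fit_trajectory_model()`). A Bayesian
   mixed-effects model describes each subject's GPI series over a natural
   cubic spline of time, $y_{ij} = x(t_{ij})^\top\theta + x(t_{ij})^\top b_i
   + \varepsilon_{ij}$, with $b_i \sim \mathrm{MVN}(0, D)$. Two internal
   knots sit at the 33rd and 66th percentiles of the observed times and
   boundary knots at 0.5 and 13 years; all full conditionals are conjugate,
   so the sampler is a plain Gibbs scheme. The subject-specific posterior
   gives the predicted value $m_i(t)$ and -- because the basis has an exact
   analytic derivative -- the slope $m_i'(t)$.

3. **Joint model** (`fit_joint_model()`). The recurrent-event hazard is
   $h_i(t) = h_0(t)\exp\{w_i^\top\gamma + A_i(t)\}$ where $\log h_0$ is a
   penalized P-spline (cubic B-splines on an equidistant grid, second-order
   difference penalty, gamma hyperprior on the inverse smoothing variance)
   and the association term $A_i(t)$ encodes one of three hypotheses:
   current value (CV) $\alpha_1 m_i(t)$; current value and slope (CVS)
   $\alpha_1 m_i(t) + \alpha_2 m_i'(t)$; cumulative effects (CE)
   $\alpha_1 \int_0^t m_i(s)\,ds$. DMT (disease-modifying therapy) exposure
   modulates the association through interaction terms
   $\delta_c\, m_i(t)\, d_{ic}(t)$ with the cumulative duration $d_{ic}(t)$
   on first-line (interferons/glatiramer) or third-line
   (natalizumab/alemtuzumab/fingolimod) therapy; untreated time is the
   reference. In the varying-coefficient variant (VCJM) the scalars
   $\alpha_k$ become cubic B-spline functions $\alpha_k(t)$ of df 4.

Counting-process construction is handled by the event engine:
`build_transitions()` turns visit records into half-open `(start, stop]`
intervals (event at stop), `classify_transition()` applies the 1-point EDSS
rule (worsening iff the score rises by at least 1.0; improvement iff it
falls by at least 1.0), `confirm_relapses()` keeps only relapse reports
accompanied by an absolute EDSS change of at least 1 point at the stop
visit, and `lag_survival_times()` shifts stop times 3 or 6 months earlier
for the PIRA-style sensitivity analysis (progression independent of relapse
activity), dropping intervals that collapse.

Person-specific prediction (`conditional_survival()`) gives
$\pi_i(u \mid t) = \Pr(T_i \ge u \mid T_i > t, \mathcal{Y}_i(t))$, updated
as marker history accumulates; models are compared by the time-dependent
discrimination $\mathrm{AUC}(t, \Delta t)$, the Brier-type prediction error
$\mathrm{PE}(t, \Delta t)$ at landmarks $t = 2.5, 5, 7.5$ years with window
$\Delta t = 2.5$, and the deviance information criterion (DIC).

## Estimation choices

**Two-stage estimation with re-sampled random effects.** Stage 3 plugs in
the stage-2 posterior means of the population parameters ($\theta$, $D$,
$\sigma$) and, by default (`resample_re = TRUE`), re-samples each subject's
spline coefficients $b_i$ inside the survival model, so the marker
uncertainty and the survival information both shape the subject-level
trajectories -- the behaviour of a fully joint fit, at a fraction of the
cost. `resample_re = FALSE` gives a fast plug-in mode that fixes $b_i$ at
the stage-2 means; it is noticeably anti-conservative for the slope
association and is intended for exploration only.

**Sampler.** Stage 3 uses Metropolis-within-Gibbs: coordinate-wise
random-walk updates for the baseline P-spline coefficients (each touches
only the rows where its basis function is non-zero), a conjugate gamma
update for the smoothing variance, block random-walk updates for the
confounder and association parameters, and a vectorised per-subject
Metropolis update for the $b_i$. Proposal scales adapt during burn-in
toward 35% (coordinate-wise) and 25% (block) acceptance and are frozen
afterwards, so post-burn-in chains are valid Markov chains and runs are
bit-reproducible given `mcmc_control()` seeds. Defaults are 3 chains of
10,000 iterations with 5,000 burn-in; all examples and tests run reduced
chains, and every fit reports split-free Gelman-Rubin factors per
parameter.

**Priors.** Fixed effects and associations have independent N(0, 10^2)
priors; precisions have Gamma(0.01, 0.01) priors; the stage-2
random-effects covariance has an inverse-Wishart prior with p + 2 degrees
of freedom and scale 0.1 I; the P-spline smoothing precision has a
Gamma(1, 0.005) prior. These are deliberately weakly informative on the
log-hazard scale.

**Numerical choices.** Survival integrals use 15-point Gauss-Legendre
quadrature per interval (verified against dense Riemann sums to a relative
1e-6). The natural cubic spline basis is built from its truncated-power
representation, so the slope and the running integral used by the CE
hypothesis are closed-form companions of the value basis rather than
numerical differences; the CE integral is therefore exact for the
piecewise-cubic marker. Event times in the simulator come from
inverse-transform sampling with bracketed root-finding on the panel-wise
integrated cumulative hazard (time tolerance 1e-8), which is exact under
any hazard specification. Ties in the stage-1 Cox fits use Breslow's
method. The Gelman-Rubin factor defaults to the classic whole-chain form
$\sqrt{((n-1)/n\,W + B/n)/W}$ -- which equals $\sqrt{(n-1)/n}$ exactly for
bit-identical chains -- with `split = TRUE` available for the split-half
variant.

**Reporting.** Posterior summaries are means with central 95% credible
intervals; hazard-ratio tables exponentiate componentwise and round to two
decimals (`to_hazard_ratio()`), the convention used for the published
association parameters, e.g. a posterior mean (CI) of 1.086 (1.068; 1.104)
for the worsening-index value association with relapse risk corresponds to
HR 2.96 (2.91; 3.02), and -1.580 (-1.880; -1.280) for the relapse-index
slope against worsening corresponds to HR 0.21 (0.15; 0.28).

## What the synthetic cohorts emulate

`simulate_disease_course()` generates "clinical-style" cohorts with the
structure the analysis assumes: 253 subjects by default, face-to-face
assessments at 0, 2.5 and 5 years then annual visits to year 15, EDSS
evolving as a first-order Markov chain on the half-point grid, relapses
from a subject-specific inhomogeneous Poisson process at a base rate of 0.3
per subject-year, four recruitment sites with distinct standardised
latitudes, roughly 40 causal SNPs with main, time- and
latitude-interaction effects on the Cox scale, and first/third-line DMT
exposure windows. The two outcome processes are coupled *only* through the
shared true GPI and covariates -- exactly the indirect-association premise
the pipeline is built to detect, so a positive generator association should
surface in the fitted $\alpha_1$, and a generator with the relapse coupling
removed should yield a credible interval covering zero.

The EDSS kernel is a stand-in: the data model only asserts first-order
Markov structure, so the generator parameterises per-interval up/down move
intensities (defaults 0.35 and 0.20 per year, scaled by interval length and
by the subject's hazard multiplier) with move sizes of 0.5/1.0/1.5 points
drawn with probabilities 0.40/0.45/0.15. These defaults were chosen once to
give a worsening-transition share near the cohort's (~20% of transitions)
and are not revisited. What the generator does **not** emulate: linkage
disequilibrium between SNPs, missing-visit mechanisms beyond administrative
censoring, MRI lesion dynamics, and EDSS measurement error distinct from
the Markov kernel. Passing recovery tests on these cohorts therefore shows
the estimator works under the model's own assumptions -- not that real EDSS
series follow this kernel.

`simulate_joint_model_data()` is the exact-model recovery harness: markers
from the stage-2 model, event times from the stage-3 hazard. The marker
schedule runs to administrative censoring because the survival side
represents recurrent events (relapses or worsening transitions), under
which subjects remain in follow-up after an event; truncating the marker at
the first event would misrepresent that design and induces exactly the
informative-truncation attenuation the recurrent-event setting avoids.

## The parameter-recovery study

The recovery conditions used by the test suite and the acceptance script
are: 300 subjects, constant baseline hazard 0.08 per year, administrative
censoring at 12 years, marker observations every 0.75 years from 0.25 to 11
years, residual SD 0.1 (the GPI is a computed index, so its measurement
noise is small), random-effects covariance diag(0.5, 0.3, 0.15, 0.15),
true associations $\alpha_1 = 1.0$ and $\alpha_2 = 0.5$, stage-2 chains of
800 (400 burn-in) and stage-3 chains of 3 x 2,000 (1,000 burn-in). Twenty
seeded replicates give mean posterior means within 0.15 of both truths with
near-nominal 95% interval coverage; the model-selection study (DIC
preferring the generating CVS structure over CV) uses 200 subjects and
single chains of 1,200. These sizes are the package's validation design;
they keep each study in the minutes range on a single core while leaving
the Monte-Carlo error well below the tolerances being checked.

## Degenerate inputs and edge behaviour

Single-visit subjects contribute no transition; visits with missing EDSS
are deleted listwise before pairing; duplicate visit times raise a data
error; off-grid EDSS values are rejected. A lag that collapses an interval
drops it. An empty SNP selection yields a null GPI model whose linear
predictor is identically zero (stage 2 then smooths a flat series and the
association is unidentified -- its posterior returns the prior, which is
the honest answer). All-identical observation times trigger a rank warning
and the regularising prior carries the trajectory fit. Fits flag
convergence failure (without discarding the draws) when every finite R-hat
exceeds 1.5.

## Known limitations

* The two outcome directions are fitted separately; there is no joint
  bivariate model of both hazards, and no multivariate longitudinal model
  of both indices.
* Stage-3 population trajectory parameters are plugged in rather than
  re-estimated, so their posterior uncertainty is not propagated; the
  re-sampled random effects carry most, not all, of it.
* The association parameters are descriptive of indirect association, not
  causal effects; nothing here implements instrument-validity or
  pleiotropy checks.
* AUC/PE censoring weights are model-based by default (consistent with a
  fully Bayesian pipeline); inverse-probability-of-censoring weighting is
  not the default route.
* Real genotype quality control, linkage structure and HLA imputation are
  out of scope; genotype input is a clean dosage matrix.
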