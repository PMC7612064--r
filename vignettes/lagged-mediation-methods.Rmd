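---
title: "Methods: lagged multilevel mediation of therapy change processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged multilevel mediation of therapy change processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagmed)
```

## The model

`lagmed` studies whether week-to-week improvement on a *process variable*
(self-focused attention, negative social cognitions, or depressed mood)
statistically transmits the effect of time-in-treatment onto a social
anxiety outcome. All variables live at level 1 (assessment occasions)
nested in participants (level 2), so this is a 1-1-1 multilevel mediation
with time as the exposure.

Temporal precedence is built in by lagging: the outcome at occasion $j$ is
paired with the process variable at the previous available occasion
$j-1$. The first occasion of each participant therefore never contributes
an outcome row, and unequal day gaps between assessments are carried into
the data rather than assumed away.

With $t$ measured in elapsed days since the first session, the two
equations are

$$
\begin{aligned}
M_{ij} &= \beta_{0M} + a_i\,\tilde t_{ij-1} + \gamma_M\,\bar t_i
          + u_{Mi} + \varepsilon_{Mij},\\
Y_{ij} &= \beta_{0Y} + b\,\tilde m_{ij-1} + c'_i\,\tilde t_{ij}
          + \gamma_Y\,\bar t_i + \delta\,\bar m_i
          + u_{Yi} + \varepsilon_{Yij},
\end{aligned}
$$

where tildes are within-person (group-mean-centered) components and bars
participant means. Path $a$ (time → process) and the direct path $c'$
(time → outcome) carry random slopes; the lagged within-person path $b$
(process → outcome) is fixed across participants, which limits model
complexity and reflects that between-person variability in this coupling
is not the target of inference. Because the covariance between a random
and a fixed path is zero, the indirect effect reduces to $ab$ and percent
mediation to

$$
P_M = 100 \cdot \frac{ab}{ab + c'}.
$$

`percent_mediation()` implements the general form
$100\,(ab+\sigma_{ab})/(ab+c'+\sigma_{ab})$ so that the optional
random-$b$ variant (`b_random = TRUE`, which estimates the slope
covariance $\sigma_{ab}$) flows through the same arithmetic. Values
outside $[0, 100]$ — which arise when the indirect and direct paths
disagree in sign — are reported as computed and flagged, never clipped.

Direction is probed by *reversed* models (`reverse_model()`): the same
lagged machinery with mediator and outcome roles swapped, so that social
anxiety at $j-1$ predicts the process variable at $j$.

## Estimation

Participants are independent; per participant the stacked
(process-equation, outcome-equation) response vector is multivariate
normal with mean from the fixed effects and covariance
$Z_i G Z_i' + R_i$, where $G$ holds the random intercepts of both
equations plus the random $a$ and $c'$ slopes (the $a$–$c'$ correlation is
estimated by default and can be switched off) and $R_i$ is diagonal with
per-equation residual variances. The lagged within-person process value
enters the outcome equation as an observed covariate; conditioning on the
observed group-mean-centered value is the classical disaggregation
approach for this design.

Numerical choices:

* Variance parameters are optimized on an unconstrained scale — log
  variances and atanh-scaled correlations — which guarantees positive
  definiteness; degenerate proposals that still fail a Cholesky
  factorization receive a large penalized objective value.
* The fixed effects are profiled out by generalized least squares inside
  every likelihood evaluation, so the optimizer (`L-BFGS-B`, relative
  tolerance ~1e-8, projected-gradient tolerance 1e-5, 500 iterations)
  works in the 7-parameter variance space only. The per-participant solves
  use the Woodbury identity (cost linear in rows, quadratic in the four
  random effects), with a dense fallback when a cross-equation residual
  covariance is requested.
* Starting values are deterministic: per-participant least-squares slopes
  give the mean and (halved, as it over-states truth by the least-squares
  noise) variance of the random slopes; pooled residual moments seed the
  residual variances. Refits are therefore exactly reproducible and
  independent of participant ordering.
* Fixed-effect standard errors are the model-based GLS covariance
  $(\sum_i X_i'V_i^{-1}X_i)^{-1}$ at the variance optimum — the mixed-model
  convention — with a cluster-robust sandwich alternative
  (`se_method = "sandwich"`) built from participant-level GLS scores.
  Point estimates are identical either way; only the SEs differ, and all
  percent-mediation arithmetic is built on point estimates. Variance
  parameters get SEs from a numerical Hessian on the unconstrained scale,
  and their Wald tests are reported on that scale with the caveat recorded
  in the output.
* The likelihood is validated in the test suite against an independent
  dense multivariate-normal oracle (tolerance 1e-8) and against lme4 on
  the process equation alone.

## Data preparation choices

* **Previous available occasion.** "Lag 1" means the most recent earlier
  occasion with an observed process value, not strictly session $j-1$:
  routine-practice data contain missed questionnaires, and the model
  absorbs the resulting unequal gaps through the recorded day distances.
  A `max_gap` cap is available for sensitivity analyses (monthly booster
  sessions are part of the protocol, so the default is unlimited).
* **Centering window.** Participant means for the within/between
  decomposition are taken over the participant's lagged rows — the records
  the model actually uses — which keeps the reconstruction
  `within + between = observed` exact in the fitted dataset.
* **Time covariate.** Raw elapsed days, group-mean centered like the
  process variable, with the participant mean entering the between level.
  The small per-day magnitudes of the slopes (≈ −0.01 to −0.04) follow
  from this unit choice.
* **Scoring.** A scale score is prorated (mean of answered items × item
  count) when at least 75% of its items are answered, else missing — a
  conventional audit rule adopted because the instruments themselves do
  not prescribe one. The SCQ composite standardizes the frequency and
  belief subscale means against all-occasion sample moments by default
  (keeping the composite comparable across treatment); a baseline-only
  window is available via `estimate_scq_params(window = "baseline")`.
* **Effect sizes.** Pre/post Cohen's $d$ uses the pooled-SD form
  $(\bar x_{pre} - \bar x_{post}) / \sqrt{(s^2_{pre} + s^2_{post})/2}$;
  this form reproduces all eight reference $d$ values bundled with the
  package to ±0.005, which is the basis for preferring it over the
  paired-difference-SD form. Confidence intervals for $d$ are not an
  inferential target here and are not implemented.

## The synthetic cohort generator

Real clinic audit data cannot be redistributed, so every stage is
exercised against `simulate_cohort()`. The generator's defaults *are* the
study conditions the package was designed around, and are not meant to be
tuned per analysis:

* 185 participants; session counts from a rounded normal (mean 12.3,
  SD 2.9) truncated to 5–26.
* Session spacing: regular gaps of about 10 days (weekly scheduling that
  slips, as it does in routine care) plus up to three end-of-treatment
  booster gaps around 40 days, yielding a mean treatment length of about
  204 days.
* True paths set to the self-focused-attention reference model
  ($a=-0.013$, $b=0.821$, $c'=-0.039$); random-slope variances
  ($3.6\times10^{-5}$, $7.5\times10^{-4}$, correlation 0.3) and intercept
  variances calibrated once so that (i) the printed "< 0.001" slope
  variance magnitudes are respected and (ii) the intraclass correlations
  of both variables land inside the .43–.68 screening band. No
  residual-variance or slope-variance magnitudes exist to copy, so these
  are calibration choices, documented as such.
* Occasion-level missingness (default 12%) models skipped questionnaires
  at attended sessions; scores are clipped to instrument bounds after
  noise, the clipping rate is reported (heavy clipping attenuates slopes),
  and configurations implying more than 50% clipping are refused.
* Lag-1 coupling uses the within-person-centered process value, matching
  the estimator; `centered_coupling = FALSE` generates uncentered coupling
  for misspecification experiments. Secondary process variables trend over
  time but are deliberately *not* coupled to the outcome, so pipeline runs
  over all three variables include built-in negative controls.

What the generator does **not** emulate: informative dropout (missingness
is independent of severity), therapist-level clustering, floor/ceiling
measurement artefacts beyond simple clipping, and item-level response
processes (an item-level mode exists only to exercise the scoring module).
Passing recovery tests therefore demonstrate estimator correctness under
the stated generative assumptions, not robustness to these real-data
features.

A known and expected consequence of honest missingness: when occasion
$j-1$ is missing, the lagged pairing falls back to $j-2$, whose true
coupling to $Y_j$ is weaker than $b$. At the default 12% missingness this
attenuates $\hat b$ by roughly 10%, which is why the recovery bands used
in validation are ±10% for $a$ and $c'$ but ±15% for $b$, and why
confidence-interval calibration is asserted for $a$ (and for $b$'s test
size under the null, where no attenuation operates) rather than for $b$
under coupling.

## Validation harness and problem sizes

The test suite (and `scripts/acceptance.R`) validates, at sizes chosen to
mirror the reference design while remaining desk-scale:

* the likelihood against a dense multivariate-normal oracle on instances
  of up to 5 participants × 4 rows (tolerance 1e-8);
* parameter recovery at 200 participants × ~12 sessions, 50 replicates
  (mean $\hat a$, $\hat c'$ within ±10%, $\hat b$ within ±15%,
  $|\text{bias}(\hat a)| < 0.0015$);
* 95% CI coverage for $a$ (within [0.90, 0.98]) and the type-I error of
  $b$'s Wald test (within [0.03, 0.07]) from 500 replicates generated
  under $b = 0$;
* ICC recovery across generating ratios {0.20, 0.43, 0.68} at
  200 × 10 (±0.05);
* exact lagging/centering identities, and byte-identical reruns of every
  randomized stage under fixed seeds.

## Known limitations

* Therapist effects are ignored (two-level model); with few therapists per
  clinic and highly variable caseloads a three-level model would be
  unstable, but the estimates are conditional on this choice.
* Path $b$ is fixed; genuine between-person heterogeneity in the
  process-outcome coupling would be absorbed into residual variance.
* Only adjacent (previous-available) occasions are modelled; delayed or
  cumulative process effects are out of scope.
* The observed group-mean centering treats the centered covariates as
  known; with few occasions per participant this understates uncertainty
  relative to latent-centering formulations.
* Between-level coefficients (regressions of the participant-level
  intercepts on mean time and mean process) are estimated and reported
  but have no external reference values; treat them as structural
  controls, not inferential targets.
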