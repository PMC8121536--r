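---
title: "Methods: staircase elicitation, discounting curves, and anxiety path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staircase elicitation, discounting curves, and anxiety path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaydisc)
```

`delaydisc` simulates and analyzes delay-discounting experiments in which the
immediate option is drawn from a fixed grid of reward levels — occlusion
levels of a photograph in the experiential task, dollar amounts in the
hypothetical task — and the delayed option is the full reward after a known
delay. This vignette records the modelling choices and their rationale, the
defaults and their units, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## The staircase and its conventions

Each (delay, run) cell runs an independent bisection over the `L` levels of
the immediate grid (levels are indexed in order of increasing immediate
value). The engine tracks the highest level the agent has *rejected* (waited
at) and the lowest level it has *accepted* immediately; a wait raises the
bracket's lower edge and an acceptance lowers its upper edge. The presented
level is the floor-midpoint of the current interval, bumped off endpoints
already tested so every trial strictly narrows the bracket; the first trial of
each cell is instead drawn from a start pool (levels 4–6 of 10 in the
experiential task, the middle three of 14 in the hypothetical task) to vary
the opening decisions. Delays are interleaved: each trial's cell is drawn
uniformly among the unconverged cells.

Two conventions are underdetermined by the task description and were fixed as
follows:

* **Convergence.** A cell is converged as soon as the candidate set maps to a
  single immediate *value*: either the bracket has width one, or only the top
  level and "never accepts" remain — both of which are worth the full reward,
  so distinguishing them would spend a trial without changing the elicited
  value. The extracted indifference point is the lowest accepted level; cells
  with no acceptance (or no rejection) map to the extreme level with an
  `at_boundary` flag rather than being dropped, because consistently patient
  participants are data, not noise.
* **Trial arithmetic.** With 10 levels this convention needs 3 or 4 trials per
  cell — exhaustively, over every deterministic threshold agent and every
  start level, `staircase_trial_census()` shows counts of exactly 3 or 4
  (mean 3.42) and *exact* recovery of the threshold's value in every case.
  A 22-cell session therefore totals between 66 (an agent and start placement
  resolved everywhere in 3) and 88 (everywhere in 4); realistic agents, whose
  effective threshold varies across delays and whose starts vary across cells,
  mix the two and typically total in the mid-70s. No halving rule can both
  keep the worst case at 80 and the best case at 70: a binary decision tree
  distinguishing the 11 possible outcomes cannot have all leaves at depth 3,
  and any depth-3 leaf admits an all-3s session.

The "Processing Data" screen duration (5 s plus the delays of all immediate
choices among the previous five trials) and the 2 s response buffer are
bookkeeping fields; nothing sleeps in simulation.

## Discounting curves and their fits

Indifference points are analyzed on the normalized scale
`SV' = (SV − SV_min)/(1 − SV_min)`, where `SV_min` is the lowest immediate
level as a fraction of the delayed reward (0.13 experiential, 0.01
hypothetical), so the grid spans [0, 1]. Two curves are fit per participant:

* hyperbolic, `SV' = 1/(1 + kT)`, `k` in 1/seconds (experiential) or 1/days
  (hypothetical);
* two-parameter logistic on the log-delay axis,
  `SV' = 1/(1 + exp(a(log T − b)))`, with `b` the log-delay at the preference
  switch and `a` its sharpness. The hyperbola is the `(a, b) = (1, −log k)`
  special case; the Rachlin power function maps to `(s, −log(k)/s)`.

Fits minimize the residual sum of squares with `optim`'s bounded
quasi-Newton method restarted from a grid (`a` in {0.25, 1, 4, 16} crossed
with five `b` values spanning `[log T_min − 2, log T_max + 2]`; `k` from nine
log-spaced starts in `[1e−6, 10]`); the best start wins, with ties broken by
lower RMSE then lower slope. Both indifference points per delay enter as
separate observations. `R² = 1 − SS_R/SS_Tot` is reported against the
participant's mean and is allowed to be negative (or `-Inf` for exactly
constant data) rather than clamped, because "the mean fits better" is a
meaningful outcome for very patient participants; `RMSE = sqrt(SS_R/n)`
measures fit quality independently of the data's spread. A three-parameter
variant with a free lower asymptote (`SV = c + (1−c)·logistic`) is available
but flagged experimental — its functional form is an assumption, not an
established result.

**AUC.** Model-based AUC integrates the fitted logistic curve over
`[T_min, T_max]` on the *linear* time axis, normalized by the interval length
— the standard AUC convention; a logarithmic axis would weight short delays
more but has no canonical normalization here. The quadrature is split at the
inflection delay `exp(b)` so arbitrarily sharp switches integrate to 1e−6
accuracy (verified against a dense trapezoid oracle).

## The linearized mixed-model framework

`y = log((1 − SV')/SV')` turns the hyperbola into the offset line
`y = log k + log T` and the logistic curve into `y = −ab + a·log T`. Three
models are fit by maximum likelihood (never REML, so likelihood-ratio tests
and AIC/BIC across fixed-effect structures are valid): per-participant means
(null), a random-intercept model with the log-delay coefficient fixed to 1
(hyperbolic), and a correlated random-intercept-and-slope model (logistic,
unstructured 2×2 covariance). The null and hyperbolic models count the same
number of parameters, so their comparison has `df = 0`; under a point mass at
zero, any positive deviance has upper-tail `p = 0`, which is how such
comparisons are reported (with a note). Marginal and conditional R² follow
the fixed/random/residual variance decomposition, with the random-slope
contribution averaged over the observed design.

**The clamp.** The transform is infinite at `SV' ∈ {0, 1}`, values the
staircase produces whenever a participant always (or never) waits at a delay.
`SV'` is clamped to `[eps, 1 − eps]` with `eps` equal to half the smallest
step between adjacent normalized grid levels (≈ 0.0115 for the experiential
grid), computed from the task configuration rather than hard-coded: the clamp
then sits just beyond the finest distinction the grid itself can make.

**What the grid can and cannot express.** The transform of a 10-level grid
spans only about `[−4.45, +1.57]` (plus `±4.45` at the boundaries). Group
slopes whose implied response range fits inside that span are recovered
essentially unbiased (shown in the test suite both by direct simulation in
`y`-space and through the full staircase at a moderate slope of 1.5). Group
slopes far above ~2, whose implied range greatly exceeds the representable
span, are *attenuated* when elicited through the grid — censoring flattens
each agent's observable response. Estimates from grid data and generating
parameters for smooth latent agents are therefore not interchangeable at
steep slopes; the package's recovery utilities
(`recovery_experiment()`) make this attenuation measurable rather than hiding
it. A related, smaller effect: the staircase reports the *lowest accepted
level*, which biases `y` downward by up to half a grid step.

## Scalar statistics

* **Welch tests from summaries** use the exact Welch–Satterthwaite degrees of
  freedom (floored for display). Cohen's d standardizes by the root mean
  square of the two SDs — the unweighted variance pooling, appropriate when
  one group is an order of magnitude larger than the other.
* **The correlation Bayes factor** integrates the exact sampling density of
  the Pearson correlation (via the Gauss hypergeometric series) against a
  stretched-beta prior with shape `1/prior_scale`; `prior_scale = 1/3` is the
  conventional "medium" default for correlation tests. The posterior median
  comes from the same quadrature, so no MCMC is needed; at r = −0.014,
  n = 44 the implementation gives BF10 ≈ 0.339.
* **The paired signed-rank test** uses the exact distribution up to 25
  informative untied pairs and the normal approximation above, and flags
  all-zero differences as degenerate.

## Path models

The anxiety path models are recursive systems over state anxiety, trait
anxiety, (optionally) reward sensitivity, and the two AUCs, estimated by
normal-theory maximum likelihood in regression (RAM) parameterization:
`Sigma = (I − B)^{-1} Psi (I − B)^{-T}`, with the exogenous variances and
covariance, the residual variances, and the residual covariance between the
two AUCs free. The optimizer starts at equation-wise least squares, which is
already exact for the saturated no-mediation model; standard errors come from
the observed information matrix. Because print conventions differ on whether
coefficients are standardized "with respect to" the predictors only or both
sides, both are reported (`std_x` and `std_all`). Fit indices: CFI against
the independence baseline, RMSEA from the noncentral chi-square (both exact
at their saturated values when `df = 0`), and SRMR from standardized residual
moments. Indirect effects are path products with delta-method standard
errors. The moderation regression keeps state and trait on their raw scales,
since the interaction coefficient is conventionally reported per raw product
unit; the split-half illustration median-splits trait anxiety and correlates
state anxiety with AUC within each half.

## The synthetic population

`population_params()` fixes the study conditions: 44 participants; state
anxiety mean 34.3 (SD 10.1) and trait anxiety mean 43.0 (SD 10.8), correlated
at 0.59 (anxiety-inventory units); experiential logistic parameters centred
on slope 4.3 and inflection 13.5/4.3 ≈ 3.14 log-seconds, hypothetical on 1.8
and 12.4/1.8 ≈ 6.9 log-days; mean reward sensitivity 0.73 (SD 0.16); rating
slope −0.55 Likert points per occlusion level with six ratings at each of the
ten levels. Between-agent SDs for the discounting parameters (1.0 for the
slope, 0.5 for the intercept on the linear-model scale) are not published
quantities; they were chosen once as dispersions that keep most agents'
switch points inside the delay grid while producing a realistic minority of
always-patient boundary agents.

Anxiety affects discounting through the inflection parameter `b` (how long an
agent will wait), not through AUC directly — AUC emerges downstream of the
staircase and curve fit, so recovered path coefficients are attenuated
relative to the structural ones and analyses should be read as sign/pattern
checks, not coefficient equalities. Reward sensitivity enters generation
inversely: each participant's rating-noise SD is solved from their target
sensitivity via `|r| = |slope|·sd(occ)/sqrt(slope²var(occ) + sigma²)`, so the
elicited absolute correlations average ≈ 0.73 by construction. Ratings are
rounded half-away-from-zero and clipped to the Likert grid [−4, 4]; the
clipping attenuates the fitted occlusion slope by a few percent relative to
the generating −0.55, which the tests bound explicitly. Choice noise is a
logistic temperature on the normalized value difference (default
`tau = 0.02`), small enough that staircases remain effectively monotone —
participants' actual choice stochasticity is not characterized, so `tau` is a
free artifact parameter.

The generator does **not** emulate reaction times, photograph-content
effects, session order, fatigue, or any systematic inconsistency in choices;
passing tests therefore validate the algorithms and their implementations,
not behavioural realism beyond the anchored moments.

## Problem sizes and determinism

The test suite works at the study's own scale where that matters (44 agents
for recovery checks, the full 22-cell staircase per agent) and at n = 2000 to
5000 only for moment-matching and path-recovery checks that need tight
sampling error; the full pipeline test runs at n = 16, the smallest size at
which the mediation model (14 free parameters) is estimable. Every stochastic
component is seeded: sessions carry a private RNG stream, and
`generate_study()` fans a single seed out to per-participant, per-task
substreams, so identical seeds give byte-identical tables and reports.

## Known limitations

* Steep-slope attenuation through the 10-level grid (discussed above) is the
  dominant caveat when relating fitted mixed-model slopes to latent agent
  parameters.
* The worst-case/best-case staircase session totals (88/66) necessarily
  bracket, rather than match, the typical 70–80 band of mixed sessions.
* The three-parameter logistic fit is experimental; its asymptote form is an
  assumption.
* Path-model inference assumes multivariate normality and complete cases;
  there is no bootstrap for indirect effects and no latent-variable support.
* The Bayes factor quadrature targets |r| < 1 and n ≥ 4; degenerate inputs
  are rejected rather than approximated.
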