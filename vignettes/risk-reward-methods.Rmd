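---
title: "Methods: direct and indirect risk-reward assessment from GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct and indirect risk-reward assessment from GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mesorisk implements three linked analyses of how a mesopredator (coyote)
navigates an apex predator (mountain lion) that is simultaneously a source
of risk and — through carrion at its kill sites — of reward: a
step-selection comparison of direct versus indirect assessments, an
encounter analysis, and a kill-site use analysis. This vignette documents
the models, their assumptions, the tunable parameters, and the design
choices made where several defensible options existed.

## Step-selection model and its generative dual

The core model is an integrated step-selection function. Each observed
hourly step (the straight-line displacement between consecutive GPS fixes)
is a stratum together with 10 *available* steps sharing its start point,
whose lengths are drawn from a gamma distribution (shape 0.38, scale
1402.57 m — the observed coyote hourly step-length fit, mean ≈ 533 m) and
whose turning angles are uniform on (−π, π] relative to the previous
bearing. Conditional logistic regression then estimates selection
coefficients β by maximizing the stratified multinomial likelihood; an
intercept cancels within strata, as does any stratum-constant covariate
(tested as an invariant).

The simulator is the *exact dual* of this model: at each simulated step it
proposes 50 candidate endpoints from the same gamma × uniform kernel and
picks one with probability ∝ exp(β·z), where z are landscape layers
standardized over the landscape. Because proposal and availability
distributions coincide, fitted coefficients are consistent for the
generative ones, and the true coefficients of step length and log step
length are zero. This is what makes parameter-recovery testing meaningful:
95% Wald intervals from the naive covariance cover the generative betas at
close to nominal rate (measured ≈ 93–96% pooled over 20 replicates of
2,000-step tracks by the acceptance checks).

Two numerical points matter here:

* **Boundary handling.** The gamma tail is heavy enough that long
  simulations diffuse tens of kilometres; no finite landscape avoids edge
  effects. Both the generative chooser and availability sampling therefore
  *reject and redraw* endpoints off the landscape. Since both sides apply
  the same per-stratum truncation, the conditional likelihood remains
  well-specified. An unconfined mode (`bounded = FALSE`, selection-free)
  exists for checking the movement kernel's sampling distribution itself.
* **Newton fitting.** The fit converges when the score norm relative to
  the stratum count drops below 1e-8, capped at 50 iterations with step
  halving; exhausted iterations or coefficients beyond ±10 on the
  standardized scale raise a separation error naming the covariate,
  never a silent return. The implementation is cross-checked against
  `survival::clogit` (coefficients to 1e-6, robust SEs to 1e-4).

## Direct metrics, indirect surfaces, model set

The direct risk covariate at a query fix is ln of the minimum over past
lion locations of distance (km) × time-since (days); the direct reward
covariate does the same over kills, with the kill's *first* lion fix as
its event time (the last fix is a configurable alternative; the choice
only shifts time-since by the residency duration). Distances are floored
at 1 m and lags at 60 s so the log is always defined; "past" is strict —
future source locations are never used, since time-since is undefined for
them. Queries with no past source propagate a missing value and the whole
stratum is dropped (interpolating or zero-filling would fabricate
information); the count of dropped strata is reported. Units cancel out of
standardized coefficients, so km·days only affects interpretability.

Indirect covariates are habitat-based occurrence surfaces in [0, 1]. They
are pluggable: externally supplied rasters (the faithful path when such
surfaces exist) or an internal probability random forest classifying used
versus available points on the landscape covariates (the testable path);
provenance is recorded on the object. The accompanying ROC utility picks
the threshold maximizing sensitivity subject to a 5% false-positive cap,
breaking ties toward the lower threshold.

Five candidate models are ranked by QIC = −2Q + 2·trace(Â·V̂ᵣ) with Â the
naive information and V̂ᵣ the cluster-robust (per-coyote) covariance: the
base habitat model (12 predictors: movement terms plus distances to
roads/aspen/forest, elevation, TPI, TRI, and four fractional cover
layers), and the four augmented combinations of {ln direct, indirect} ×
{kill, lion} that carry 14 predictors each. When robust and naive
covariances agree the trace is exactly K (tested to 1e-9). Candidate
habitat covariates are first screened by iterative VIF pruning (drop the
max until all < 3, ties toward table order, removals logged) and all
predictors are centred and scaled.

The default synthetic scenario gives coyotes an avoidance of the indirect
lion surface (β = −0.5), an attraction to the indirect kill surface
(β = +0.3), mild shrub/bare-ground habitat effects, and *no* response to
the direct metrics. Both indirect terms are non-null by design: with a
single indirect effect the two top candidate models would differ only by a
noise covariate and their ranking would be a coin flip, whereas the
intended property — the indirect-only model winning — reflects indirect
assessments of both risk and reward driving behaviour. Under this truth
the indirect-only model ranked first in 20/20 replicate scenarios.

## Encounters

An encounter pair is one coyote fix and one lion fix within 1 km and 2 h
(both inclusive — the conservative reading; both thresholds are
arguments). Consecutive qualifying coyote fixes of a dyad merge into a
bout; the bout ends when the criterion fails for longer than the fix
interval (plus a 5-min schedule tolerance). Encounters are pooled per
coyote and dropped when they start strictly within 5 h of the previous
retained encounter's *end* — measured from the end because an encounter
cannot follow one that has not finished. The detection sweep is verified
to equal the brute-force double loop exactly on hundreds of random track
pairs.

Movement rate (m/h, consecutive-fix displacements wholly inside the 5-h
pre/post windows, bout fixes excluded) is modelled with a gamma (log link)
GAMM: a thin-plate smooth of signed time-to-encounter (negative before the
start, positive after the end), a cyclic cubic smooth of hour of day
wrapping at 24 h, and ridge-penalized random intercepts for coyote and for
encounter nested within coyote. Rates of zero are floored at 1 m/h (gamma
support) and counted. The 10-h-window step-selection model samples
available steps with pre- and post-encounter gammas (0.38/1177.75 and
0.41/1413.39) to preserve the observed movement difference, and uses
cos(turn angle), shrub and tree proportions in a 256-m-diameter buffer
(half the mean step length), TRI, and distance to the most recent lion
fix, each also interacted with time-to-encounter; the time-to-encounter
main effect is stratum-constant and drops out.

## Kill-site use

For each kill accessible to coyotes (≥ 1 coyote fix within 1000 m,
inclusive, during the 14 days before/after the first lion fix), daily use
of ten concentric rings is recorded. Rings are upper-inclusive annuli
(100(k−1), 100k] m — a fix at exactly 100.0 m is ring 1 — and day bins are
24-h intervals counted from the first lion fix (post-kill day d covers
[(d−1), d) × 24 h; pre-kill days mirror it as −1…−14). Each window
contributes exactly eligible-kills × 10 × 14 records. Binomial GAMMs with
smooths of day and ring-midpoint distance, the fix-rate-adjusted count of
coyote fixes within 2500 m as a fixed effect, offsets for log ring area
and log inverse fix rate, and a per-kill random intercept are fitted
separately pre and post; the post model's lion-activity flag passes
through backwards AIC elimination. Fix rates are obtained/expected hourly
fixes of contributing collars (those with fixes within 2500 m during the
window), averaged when several contribute.

A subtlety worth recording: under the ring-area offset, "no spatial
pattern" means constant use intensity *per unit area*, not constant
probability per ring; null-shrinkage tests generate the former.
Prediction curves are reported at the innermost ring's area, unit fix
rate, and the median local count, matching a single-curve presentation.

## Smoothing engine

All penalized smooths are delegated to mgcv (the standard penalized-IRLS
machinery: B-spline/thin-plate bases with second-derivative penalties,
cyclic cubic bases, random intercepts as ridge terms, offsets entering
the linear predictor additively as logs), wrapped behind a small surface
(`build_basis`, `fit_pgam`, `backwards_aic`, `predict_with_ci`) so the
rest of the package is agnostic to the backend. Smoothing parameters are
chosen by GCV by default (deterministic given the data); REML is an
option. Basis dimensions default to k = 10 generally and k = 8 for the
kill-site smooths (day has 14 distinct values, distance 10). EDF p-values
are Wald-type approximations on penalized terms and are flagged
approximate. Confidence bands are normal intervals on the linear
predictor mapped through the inverse link; random-effect terms are
excluded from predictions by default so curves are population-level.

## What the generator does and does not emulate

It emulates: 30-m landscape rasters with controllable spatial
autocorrelation, the hourly coyote fix schedule of the summer season with
89.8% fix success, gamma-distributed step lengths, selection acting on
landscape layers, 3-h lion fixes alternating travel with exponential
kill-site residencies of mean 4.50 days, and kills of large prey. Lions
get a 30-day head start so early-season coyote fixes always have past
risk/reward sources, and a lion whose draw produces no kills has its seed
redrawn deterministically.

It does not emulate: home-range fidelity (confinement is by landscape
boundary, not attraction centres), behaviourally mediated encounters
(simulated coyotes neither flee nor seek lions, so encounter analyses test
null recovery rather than effect recovery), GPS positional error,
multi-year demography, or carcass biomass decay. Passing tests therefore
demonstrate statistical correctness and recoverability of injected
structure — not that real coyotes behave like the simulator.

Lion travel speed (mean ~1 km per 3-h fix) and kill spacing (≈ 1 kill per
7 travel-days) are free simulator parameters recorded in the scenario
truth; nothing downstream depends on their exact values.

## Problem sizes

The shipped checks use sizes chosen to exercise every code path at
comfortable statistical power: 20 replicate 2,000-step tracks for
coefficient recovery; 20 replicate two-coyote scenarios of 600 steps for
model-ranking recovery; 25-kill synthetic record sets for the kill-site
curve recovery; 10,000 draws for sampling-distribution checks; ~200
random fixtures for each brute-force oracle comparison. The default
demonstration scenario (three coyotes × 1,000 steps, two lions) runs the
full workflow in about a minute on one CPU.

## Known limitations

* Robust sandwich covariances need several clusters; with one animal the
  robust SE degenerates to zero and the naive covariance should be used
  (exposed as `se_naive`).
* The random-intercept GAMM treatment of nested coyote/encounter effects
  is the standard ridge approximation, not a full mixed-model likelihood.
* The internal occurrence classifier is a generic probability forest; it
  stands in for externally estimated predator/kill occurrence models and
  makes no attempt to reproduce any particular field-fitted model.
* Step-length distributions are fixed at their supplied parameters; no
  iSSA-style tentative-to-updated movement-kernel correction is applied.
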