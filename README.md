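# mesorisk

Movement-ecology tools for asking how a mesopredator navigates the risk and
reward created by an apex predator — built around the coyote (*Canis
latrans*) / mountain lion (*Puma concolor*) system, where lions are both a
mortality risk for coyotes and, through the carrion at their kill sites, a
food source. The package is aimed at spatial ecologists working with GPS
telemetry who want to compare **direct** assessments of risk/reward (built
from the actual positions and times of predators and kills) against
**indirect** assessments (habitat-based occurrence surfaces), and to analyse
behaviour around discrete encounters and kill sites.

Everything runs end-to-end on synthetic data with known ground truth: a
landscape generator, a correlated-random-walk coyote simulator whose steps
are biased by known selection coefficients (the generative dual of the
model being fitted), and a lion simulator with multi-day kill-site
residencies.

## The models

**Integrated step-selection functions (iSSF).** Each observed hourly step is
paired with 10 available steps (gamma step lengths, shape 0.38, scale
1402.57 m; uniform turning angles on (−π, π]). Conditional logistic
regression maximises

&nbsp;&nbsp;Σ_s [ η_s,obs − ln Σ_j exp(η_s,j) ],&nbsp;&nbsp; η = **x**′β,

with a cluster-robust sandwich covariance (scores summed within coyote).
Five candidate models — a base habitat model (step length, ln step length,
distances to roads/aspen/forest, elevation, TPI, TRI, and shrub/bare/
herbaceous/sage fractions) plus four combinations of direct and indirect
risk/reward terms — are ranked by the quasi-likelihood under independence
criterion,

&nbsp;&nbsp;QIC = −2Q + 2·trace(Â V̂_r),

where Â is the naive information and V̂_r the robust covariance; the trace
reduces to K when the two covariances agree.

**Direct metrics.** At a query location/time, the direct risk (or reward)
covariate is ln of min over past sources of [distance (km) × time-since
(days)], the minimum picking the most spatiotemporally relevant lion
location (or kill).

**Encounters.** A coyote–lion encounter is a bout of fix pairs within 1 km
and 2 h; bouts end when the criterion fails, and encounters starting within
5 h of the previous one are discarded. Movement rate in the 5 h before/after
is modelled with a gamma GAMM (smooth of time-to-encounter, cyclic smooth of
hour of day, nested coyote/encounter random intercepts); habitat selection
in the 10 h before/after with an iSSF whose covariates interact with signed
time-to-encounter.

**Kill-site use.** Daily coyote use of ten concentric 100-m rings around
each kill, for 14 days before and after the first lion fix, is modelled with
binomial GAMMs (smooths of day and distance, ring-area and fix-rate offsets,
per-kill random intercept, backwards-AIC screen of the lion-activity flag).

## Worked example

```r
library(mesorisk)
sc <- simulate_scenario(seed = 1)      # landscape + 3 coyotes + 2 lions + kills
ic <- run_issf_comparison(sc, seed = 1)
ic$ranking
```

```
                     model  quasi_ll  K      qic delta_qic
             indirect_only -4966.104 13  9956.33   0.00000
 direct_kill_indirect_lion -4997.643 13 10019.72  63.39193
 indirect_kill_direct_lion -5135.226 13 10290.24 333.91066
                      base -5181.799 11 10383.29 426.96222
               direct_only -5181.657 13 10384.01 427.68081
```

The scenario's coyotes were simulated to avoid the indirect lion surface
(β = −0.5) and seek the indirect kill surface (β = +0.3) while ignoring the
direct metrics, and the ranking recovers exactly that structure: the
indirect-only model wins decisively and the two models containing the
indirect lion term dominate the rest. The best-model coefficients show the
injected effects with the right signs:

```r
subset(ic$coef_table, predictor %in% c("IndirectLion", "IndirectKill"))
#      predictor   beta    se      z       p
#   IndirectKill  0.262 0.029   9.14 6.3e-20
#   IndirectLion -0.630 0.034 -18.80 7.9e-79
```

One habitat covariate (the aspen/forest distance pair is strongly
correlated by construction) is VIF-pruned before fitting, which is why the
base model carries 11 predictors here rather than its full 12.

The numbered scripts under `analysis/` run the full workflow stage by stage
(`01_simulate.R`, `02_issf_comparison.R`, `03_encounters.R`,
`04_killsites.R`), printing what each stage found and writing tables under
`results/`.

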