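---
title: "Substrate-modulated growth models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-modulated growth models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oxyglulac)
```

## The model family

`oxyglulac` models the population dynamics of a single, non-differentiating
cell line (the motivating system is the BEAS-2B human bronchial epithelial
line) growing in static well-plate culture, coupled to the three metabolic
substrates that matter most for epithelial cell viability: dissolved oxygen
$c_o$, glucose $c_g$ and lactate $c_l$ (all in mol m$^{-3}$). With spatially
homogeneous submerged culture, mass balances reduce to ODEs:

$$
\frac{dn}{dt} = f_1(c_o)\, f_2(c_g)\, f_3(c_l)\;
  \beta\, n \left(1 - \frac{n}{n_{max}}\right) - \delta\, n
$$
$$
\frac{dc_g}{dt} = -\tilde n\, V_g \frac{c_g}{c_g + \bar c_g}, \qquad
\frac{dc_l}{dt} = +2\, \tilde n\, V_g \frac{c_g}{c_g + \bar c_g}
  - \frac{1}{3}\, \tilde n\, V_o \frac{c_o}{c_o + \bar c_o}, \qquad
\frac{dc_o}{dt} = 0 .
$$

Here $n$ is cells/well, $\tilde n = n/10^6$, $\beta$ is the proliferation
coefficient, $\delta$ the apoptosis rate, and $n_{max}$ the logistic
carrying capacity. Each modulating factor $f_k$ is one of: constant 1
(zero-order), proportional $c$ (first-order), or saturating
Michaelis–Menten — $c/(c+K)$ with positive feedback for oxygen and glucose,
$K/(c+K)$ with negative feedback for lactate (lactate accumulation inhibits
growth). Three choices per substrate give $3^3 = 27$ candidate models
(`enumerate_candidates()`); models are named by their MMK substrates
(`OxyGluLac` = all three saturating).

Assumptions worth stating plainly:

* **Oxygen clamp.** Dissolved oxygen is held constant at the
  incubator-equilibrium level: atmospheric diffusion replenishes what cells
  consume, and $K_o$ still enters through $f_1$. Incubator percentages map
  linearly to concentration via `oxygen_percent_to_conc()` (18.6 % →
  0.18 mol m$^{-3}$).
* **Lactate stoichiometry.** Glycolysis produces two lactate molecules per
  glucose consumed; oxidative respiration removes lactate at one third of
  the oxygen consumption rate. The printed source for this equation is
  typographically ambiguous about signs; the convention above is the only
  one under which lactate accumulates during culture, as observed. It is
  switchable (`fixed_constants(lactate_sign = -1)`, config key
  `lactate_sign`) for anyone wanting the literal alternative.
* **Units.** Time is hours at every interface and seconds inside the
  solver; concentrations are mol m$^{-3}$; populations are cells/well. The
  consumption constants $V_g$, $V_o$ are expressed *per $10^6$ cells*. This
  choice is deliberate: published per-cell magnitudes (~$10^{-19}$) are
  dimensionally doubtful and would fall outside the calibration hypercube
  $[10^{-7}, 10^7]$; scaling by $10^6$ puts all seven calibrated parameters
  inside it without changing the dynamics.
* **Carrying capacity.** $n_{max}$ is a fixed constant, not calibrated; no
  reported value exists for the motivating study, so the synthetic default
  is $3\times10^6$ cells/well — high enough that saturation is visible
  within 114 h only from the largest seeding.

### Structural dependence filter

A two-way ANOVA in the motivating study established that both oxygen and
glucose affect the observed populations. Models whose population equation
is structurally independent of either substrate are therefore discarded
before calibration. Dependence can be direct (a non-zero-order modulating
term) or routed through lactate: when $f_3$ is active, glucose reaches
$dn/dt$ through glycolytic lactate production and oxygen through the
oxidative lactate sink. `filter_candidates()` applies this rule; on the
full family it discards exactly the 5 models combining zero-order lactate
with a zero-order oxygen or glucose effect, keeping 22.

## Numerical integration

A compiled adaptive Dormand–Prince 5(4) integrator with step-to-output-time
(`rtol` $10^{-8}$, per-state `atol` $10^{-10}\max(1,|y_0|)$ by default)
drives all simulation. States are clipped at zero after each accepted step
— MMK terms are defined at zero, but solver error on first-order terms must
not push states negative — and clip events are counted in the trajectory
attributes. Objective evaluations use looser tolerances ($10^{-6}/10^{-8}$)
and a hard per-solve step cap so that pathological parameter proposals fail
fast with a penalty value ($10^{12}$) instead of stalling the search.

## Synthetic experiments

`default_design()` emulates the motivating study's layout: {high glucose 25,
low glucose 5.5} × {oxygen 0.18, 0.05 mol m$^{-3}$} environments, seedings
{25,000, 50,000, 100,000, 200,000} cells/well (16 conditions), 9 replicates,
sampling 6 h after seeding and then periodically with the terminal sample
forced to 114 h (a 24 h grid started at 6 h cannot land on 114 h otherwise).
Initial lactate defaults to 2 mol m$^{-3}$ (fresh-media low end;
configurable). Observations follow the multiplicative noise model
$Z = z(1 + \epsilon\eta)$, $\eta \sim N(0,1)$, floored at zero with the
floor count logged; the study-like default is $\epsilon = 0.187$.

The 60/20/20 calibration/selection/validation split is stratified within
condition on (time, observable) cells, keeping all replicates of a cell
together so that per-cell standard deviations remain computable in every
split; apportionment is largest-remainder, so each condition is represented
in every split.

**Two parameter fixtures ship with the package, and the difference is a
design decision, not an accident.** `reference_params()` carries the
literature-anchored magnitudes for calibrated BEAS-2B growth; at those
values the half-saturation constants lie far outside the observable
concentration ranges, substrate modulation is nearly inert within 114 h,
and most parameters are *practically unidentifiable* from the emulated
design — faithful to the study regime, and the right fixture for
sensitivity analyses of that regime, but useless for testing recovery or
identifiability machinery. `fixture_params()` keeps $\beta$, $\delta$,
$\bar c_g$ at study magnitudes but places $V_g$ and the $K$'s inside the
observable ranges ($K_o = 0.05$, $K_g = 2$, $K_l = 8$ mol m$^{-3}$,
$V_g = 6\times10^{-5}$ per $10^6$ cells), yielding visible glucose
depletion, lactate build-up to growth-inhibiting levels, and finite
profile-likelihood intervals for all seven parameters. Both are synthetic
stand-ins; neither claims to reproduce wet-lab numbers. A green test on
synthetic data establishes that the machinery recovers a known
data-generating process of the assumed form under the stated noise model —
not that real cultures obey the model, nor that real noise is
multiplicative Gaussian.

## Calibration

The loss is the inverse-variance-weighted nonlinear least squares
$$
LS(\Theta) = \tfrac12 \sum_{j,k} \sigma_j(t_k)^{-2}
  \left(\bar Z_j(t_k) - z_j(t_k,\Theta)\right)^2,
$$
equivalent (up to an additive constant) to Gaussian maximum likelihood of
the replicate means with known per-point variances; the $\tfrac12$ factor
is kept package-wide and every quantity derived from the likelihood uses
the same convention, so rankings and thresholds are internally consistent.
Zero replicate deviations (noiseless fixtures) are floored at
$\max(10^{-12}, 10^{-3}|\bar Z|)$.

Search runs in $\log_{10}$ space over $[10^{-7}, 10^7]^7$:

1. a Latin hypercube pool of `prescreen * n_starts` points (one cheap
   objective evaluation each) is reduced to the `n_starts` best feasible
   points — most of a 14-decade hypercube produces divergent or
   non-integrable dynamics, and screening is what makes desk-scale budgets
   reliable (set `prescreen = 1` for the plain LHS behaviour, which uses a
   maxi-min-improved hypercube);
2. projected Adam in log space (default 100 iterations, step 0.05),
   gradients by central finite differences (step $10^{-6}$);
3. L-BFGS-B refinement of the best `n_refine` stage-1 solutions, never
   accepted if it degrades the loss it started from.

The full start-loss archive is returned: on every fixture we have examined
it shows multiple distinct local optima, which is precisely why the
multi-start design exists.

## Selection, validation, identifiability

Calibrated models are re-scored on the selection split and ranked by
$BIC = k\log m_s - 2\ell$ (natural log; AIC reported alongside), ties
broken by parameter count then name. Nested-limit structure
(`nested_limit_check()`) explains near-ties: the all-MMK model reduces to
any of its relatives as $K_l \to \infty$ (negative feedback) or
$K \to 0$ (positive feedback), and the limit is numerical, not just formal
— $K_l = 10^9$ reproduces the zero-order-lactate trajectories to <0.1 %.

Validation reports the mean relative prediction error
$\frac1m \sum |\bar Z - z|/\bar Z$ (the "root of the square" in the source
formula reduces to an absolute value pointwise; some authors label this
RMSE) and the replicate noise $\frac1m \sum \sigma/\bar Z$, each averaged
with equal weight per (observable, time) point — the per-point/per-observable
weighting question is decided in favour of equal per-point weight and
exposed through `dataset_summary()` should anyone want otherwise.

Practical identifiability uses profile likelihood: each parameter is fixed
on an outward-walking $\log_{10}$ grid (step 0.05 for 40 points per side,
then doubling) while the remaining six are re-optimised, warm-started from
the neighbouring grid point. The confidence set is
$\{\theta_i : PL(\theta_i) \le L(\Theta^*) + \Delta\}$. The literal source
formula reads $\Delta = \Delta_\alpha$ (the $\chi^2_1$ quantile), but with
$L$ equal to the negative log-likelihood the standard likelihood-ratio
construction requires $\Delta_\alpha/2$; the package defaults to
`likelihood_ratio` and offers `paper_literal` as a config switch, which
widens every interval by a factor $\sqrt2$ on a quadratic objective. A
parameter is identifiable when both interval ends are crossed before the
walk reaches ten times the search bounds or its point budget.

## Sensitivity analysis

Variance-based Sobol indices of the controllable culture conditions
(oxygen clamp, initial glucose, seeding density, independent uniform over
the experimental ranges) are estimated from Saltelli paired matrices
($n_{base}(d+2)$ model evaluations; the package reads the study's "40,000
Monte Carlo samples" as total evaluations, so $n_{base} = 8000$ at
$d = 3$), with the Saltelli-2010 first-order and Jansen total-order
estimators and row-bootstrap confidence intervals. `gsa_over_time()`
reuses one evaluation design across a time grid to track how sensitivity
of the population shifts from the seeding density (all of it at $t = 0$)
toward the substrates as the experiment unfolds.

## Protocol design and the refreshment study

`protocol_sweep()` implements simulate → corrupt → re-infer → score:
for each sampling period and noise level it generates a synthetic dataset
from assumed parameters, re-fits at a reduced budget, and records the
parameter-recovery error. The default error is the *elementwise* mean
relative error $\frac1p\sum_i |\theta_i - \theta_i^*|/|\theta_i|$ — with
parameters spanning many orders of magnitude, the literal vector-norm
ratio is dominated by the largest component; both modes are implemented.
`recommend_period()` returns the coarsest period within 10 % of the best
mean error, encoding "denser sampling that does not improve inference is
not worth its cost".

`simulate_with_refreshment()` integrates piecewise between media-change
events at multiples of the period (no event at $t=0$; an event coinciding
with the horizon is not applied), resetting glucose and lactate (subset
configurable) to initial values while the population is continuous across
the event. Event times appear twice in the output trajectory — pre- and
post-reset — so the discontinuity is explicit. With the informative
fixture, refreshing every 2–10 days holds a stable population over 43
days, oscillation amplitude grows with the period, and periods beyond
about two weeks let glucose exhaustion and lactate build-up crash the
culture; under `reference_params()` substrates never deplete and the sweep
is (correctly) flat.

## Numerical and design choices, collected

* Solver: stiff-tolerant adaptive RK45; clip-at-zero with logged events;
  step cap + penalty inside objectives.
* $\sigma$ floor $\max(10^{-12}, 10^{-3}|\bar Z|)$; keeps noiseless
  fixtures finite without reordering fits.
* Tie-breaks in ranking: BIC, then $k$, then name (deterministic output).
* Split apportionment: largest remainder per condition; all replicates of
  a cell share a split.
* Config dialect: JSON (`jsonlite`), schema-validated with unknown keys
  rejected; one `RunManifest` per pipeline run records seeds per stage.
* Seeds: every stochastic entry point takes one; identical inputs and
  seeds give bit-identical outputs.

## Known limitations

The generator emulates design, schedule and replicate dispersion, not
instrument drift, well-edge effects, imaging miscounts, or non-Gaussian
heavy tails in real replicates. The weights use the replicate standard
deviation (as the source formulation does), not the standard error of the
replicate mean, so absolute interval widths inherit that convention.
Profile walks at doubled steps can overshoot a narrow re-entrant interval
in principle (none observed on the fixtures). The CLI is a thin dispatcher
over the package functions; heavy campaigns are better scripted directly
against the API.
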