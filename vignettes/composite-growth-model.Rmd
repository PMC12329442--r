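---
title: "A composite metabolic-allometric model of human growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A composite metabolic-allometric model of human growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compgrowth)
```

## The model

`compgrowth` models a child's height and weight as the sum of five gated
growth processes, each a Pütter/von Bertalanffy balance between anabolism
and catabolism on a stylised cylindrical body segment.  For one process,
mass changes as

$$\frac{dm}{dt} = Hs - Km,$$

where $s$ is the absorbing (intestinal) surface, $H \ge 0$ is mass
synthesized per unit surface per year and $K \ge 0$ is mass destructed per
unit mass per year.  With the segment stylised as a cylinder of height $h$,
radius $r$, surface $2\pi r h$ and the allometric closure $r = h^q$
($0 < q < 1$), the longitudinal growth rate becomes

$$\frac{dh}{dt} = h^{1-q}\left(\frac{2H}{D(1+2q)} -
  \frac{K}{1+2q}\,h^{q}\right),$$

with density $D$ (1 g/cm³ by default).  This has the closed-form solution
implemented in `component_height()`,

$$h(t) = \left[\frac{2H}{DK}\left(1 -
  e^{\frac{Kq}{1+2q}(i-t)}\right)\right]^{1/q}, \qquad t \ge i,$$

where $t$ is *total age in years since conception* and $i$ is the age at
which the process initiates.  The corresponding mass is
$m(t) = D\pi h(t)^{1+2q}$ (`component_mass()`).  Each process approaches
the asymptote $(2H/(DK))^{1/q}$.

A whole trajectory is the gated sum of five such processes
(`composite_height()`, `composite_mass()`), with $i_1 = 0$ at conception
and the remaining initiation ages ordered.  The five processes are
conventionally labelled in-utero, infancy, early childhood, mid-childhood
and puberty by position; nothing in the fitting fixes them to age ranges a
priori.  The model separates *metabolic* causes of growth variation (the
$H_x$ and $K_x$, plausibly shaped by diet and disease) from *allometric*
ones (the $q_x$, plausibly under stronger genetic control) — the package's
reason for being.

Parameters of one process live in `component_params(H, K, q, i)`; a
person's full 20-parameter set is a `composite_params` (5 processes × 4
parameters, with $i_1$ fixed at 0, leaving 19 free quantities).

## Data conventions

All ages are total ages since conception; birth sits at 0.75 yr (a fixed
nine-month gestation, configurable in `load_measurements()`).  Weights are
grams internally.  `prepare_dataset()` applies two conventions the
estimator expects:

* **conception anchoring** — every person gets a pseudo-observation at
  $t = 0$ of egg-cell size: height 0.012 cm, weight $1.02\times10^{-6}$ g.
  Anchors enter the likelihood exactly like observed records.
* **carry-forward densification** — each person's last observed height and
  weight are duplicated at integer ages since birth up to 26, so the adult
  plateau constrains the asymptotes.

The package never smooths measurements.

## Measurement model and multilevel structure

Observed height and weight are lognormal around the trajectory plus the
egg-cell offsets:

$$\ln h_{jt} \sim \mathrm{Normal}\!\left[\ln(0.012 + \eta_{jt}),\,
  \sigma_\eta\right], \qquad
  \ln m_{jt} \sim \mathrm{Normal}\!\left[\ln(1.02\times 10^{-6} +
  \mu_{jt}),\, \sigma_\mu\right],$$

fit simultaneously to both modalities, sexes separately.  Person $j$'s 19
transformed parameters ($\log H_x$, $\log K_x$, $\mathrm{logit}\,q_x$, and
log initiation-age increments, which enforce every printed constraint by
construction) decompose as baseline mean + group offset + person offset.
Person offsets covary across the five processes *within* each parameter
family (four independent covariance matrices) — the minimal reading of
offsets that "covary across growth processes"; cross-family covariance is
not modelled.

Priors (see `cg_priors()`): Normal baseline means centred on the
reference-like preset with SD 0.5; Normal(0, 0.5) group offsets;
conjugate inverse-Wishart person-offset covariances (df $= d + 2$, scale
$0.02\,I$, so the prior mean matches the generator default); half-Normal
measurement SDs with scale 0.05 for height and 0.25 for weight.  The
deliberately tighter height scale makes height dominate fit quality when
the rigid $r = h^q$ coupling cannot reconcile both modalities — soft-tissue
growth that adds weight without height is outside the model.

For temporally sparse populations the intended workflow is two-stage:
fit the densely measured reference population first, then derive
informative priors from that fit with `priors_from_fit()` (prior means at
the reference posterior means, SDs at twice the reference posterior SDs,
floored at 0.05) and fit the sparse population with them.  Sparse designs
that start at age one carry no early-life information of their own beyond
the conception anchor, so without reference-derived priors their
in-utero and allometry parameters remain prior-dominated and far more
uncertain than a dense fit's.

### Why these priors and this sampler

Stan-style gradient-based samplers usually pair such models with
non-centred parameterizations and LKJ priors.  This package ships its own
blocked Metropolis-within-Gibbs sampler (`fit_growth()`), and the design
choices follow from that: a centred parameterization makes the baseline
means, group offsets and covariances *exactly* conjugate (Gibbs), and an
inverse-Wishart prior keeps the covariance update closed-form.  Person
parameters move by adaptive random-walk proposals: per-family blocks
shaped by the current covariance, per-coordinate sweeps, and full
19-dimensional proposals whose per-person covariance is learned during
warmup (these follow likelihood ridges that cross families, such as the
$\log H$–$\log K$ trade-off that keeps an asymptote fixed).  Translation
moves shift a population-level coordinate together with the same
coordinate of every affected person, letting the population level traverse
its posterior directly.  Chains start from per-person ridge-penalized mode
searches (jittered per chain): the timing parameters give the person-level
posterior well-separated local modes, and short random-walk warmups do not
reliably cross between them from arbitrary starts.

Every stored draw satisfies the constraints ($H, K > 0$, $q \in (0,1)$,
ordered initiation ages) by construction of the transformed scale.
Diagnostics report split-R-hat and effective sample sizes for all
population-level parameters; acceptance rates per move type are attached
to the fit.  The sampler is not gradient-based; divergence counts (an
HMC-specific diagnostic) do not apply.

## The synthetic-data generator

`population_config()` + `simulate_growth_data()` generate study data with
exactly the statistical structure the estimator assumes.  Defaults are the
package's study conditions:

* **Preset means** (`reference_composite()`): a synthetic parameter set —
  *not* an estimate from any real population — whose female composite
  curve has adult height ≈ 165 cm, birth length ≈ 46 cm and peak pubertal
  velocity ≈ 8.6 cm/yr near age 12 since birth (males ≈ 176 cm, peaking
  near 13.5).  Components were parameterized by asymptote, approach rate,
  allometry and initiation (`component_from_shape()`) and chosen once to
  match those shape targets.
* **Person-offset covariance** $0.02\,I$ per family (SD ≈ 0.14 on the
  transformed scale, i.e. roughly ±15% parameter variation person to
  person).
* **Measurement SDs** $\sigma_\eta = 0.03$, $\sigma_\mu = 0.08$ (log
  scale).  These are fixture choices; the motivating designs do not print
  their estimates.
* **Dense design**: birth, quarterly ages to total age 2.5, annual to
  18.75, plus annual adult-horizon ages to 26.75 (the design's
  carry-forward horizon, simulated as model-consistent measurements) —
  about 33 measurements per person.  Duplicating last observed values onto
  still-growing synthetic trajectories would be a model–data mismatch, so
  the generator emulates the densified design directly.
* **Sparse design**: per-person measurement counts from the mixture
  $P(1,2,3) = (0.70, 0.29, 0.01)$ — chosen to reproduce a 70% singleton
  share, a maximum of 3 and a mean ≈ 1.3 simultaneously — at distinct
  integer ages since birth uniform on 1..24.

What passing tests on such data do **not** show: robustness to age
mis-recording, secular trends, manual smoothing of source data,
non-lognormal error, or soft-tissue (body-composition) growth.  Real
datasets carry all of these.

## Posterior summaries

* `hpdi()` — shortest contiguous interval containing
  $\lceil \mathrm{mass}\cdot n\rceil$ sorted draws (earliest window on
  ties).
* `contrast_draws()` — elementwise group differences; a difference is
  flagged detectable when its 90% HPDI excludes zero.
* `weighted_parameter_trajectory()` — the age-resolved across-process
  summary $\bar q(t) = \sum_x w_x q_x$ with weights
  $w_x = h_x / \sum_y h_y$; metabolic families are additionally weighted
  by declining metabolic activity,
  $\bar K(t) = \sum_x w_x a_x K_x / \sum_x w_x a_x$, with
  $a_x(t) = 1 - \rho\, h_x(t)/h_x(\infty)$ (`metabolic_activity()`).
  The activity form is the simplest monotone interpolation between no
  decrement at initiation and decrement $\rho$ at the asymptote
  (red-marrow replacement by marrow fat); $\rho$ defaults to 0.75.  H and
  K are treated symmetrically (same $\sum w a$ denominator).
* `trajectory_descriptives()` — per draw: height at a reference adult age
  (26 since birth, matching the densification horizon, rather than the
  asymptote), and the pubertal velocity peak searched on a 0.01-yr grid
  over ages 5–20 since birth with local refinement, earliest age on ties.
  The window isolates the pubertal peak from the infancy velocity decline;
  draws whose maximum sits on the window's lower edge are flagged
  degenerate rather than silently reported.

## Intervention simulation

`apply_intervention()` performs the counterfactual at the heart of the
package's applied use: replace some of a target group's metabolic
parameters ($H$'s and $K$'s only — allometry and timing are excluded by
construction) with the reference group's estimates, on the transformed
scale, and regenerate all downstream summaries.  Person-level offsets are
retained, modelling a population-level intervention that leaves
inter-individual variation intact.  Two modes: substitute the reference
posterior *mean* (default), or pair draws to propagate reference
uncertainty; both are provided because either reading of "set to the
reference estimate" is defensible.  `intervention_presets()` ships the
full metabolic swap and the targeted two-slot presets ({K2, H3} female,
{K2, K3} male).  These simulations are idealized: each parameter is
treated as independently modifiable, which real interventions are not.

## Numerical choices

* The saturating bracket $1 - e^{Kq(i-t)/(1+2q)}$ is clamped at $\ge 0$ to
  absorb floating-point underflow at $t \approx i$; velocities at $h = 0$
  evaluate to their limit value 0 (valid because $1 - q > 0$).
* $H, K$ are constrained strictly positive (rather than $\ge 0$) so
  logarithms, asymptotes and $1/q$ powers stay finite; an absent process
  is represented by a numerically negligible $H$.
* Overflowing powers (pathological $q \to 0$ with large $2H/K$) raise an
  error naming the offending parameters instead of propagating `Inf`.
* Components are ordered by initiation age with ties keeping input order.

## Problem sizes

The shipped tests exercise: oracle equivalence on 100 random parameter
sets against adaptive ODE integration (`deSolve`, relative error
$\le 10^{-6}$); schedule statistics at $n = 10^5$ persons; and a two-group
recovery study of 30 dense + 60 sparse persons fit with 2 chains × (500
warmup + 500 draws), the package's reference reduced-MCMC protocol, for
which 90% HPDIs are expected to cover at least 80% of the transformed
baseline means and to recover the sign of an injected group contrast in
$\log K_2$.  Those sizes keep a full check-out under half an hour on a
single core while remaining informative; larger runs simply raise
`iter`/`warmup` and the simulation sizes.

## Known limitations

* **Metabolic attribution from sparse data is wide.**  A group-level
  height deficit in a process whose active ages a sparse design barely
  samples (e.g. infancy, for measurements starting at age one) can be
  attributed to higher catabolism or lower anabolism: both lower the
  process asymptote $(2H/(DK))^{1/q}$, and only rate information — scarce
  at those ages — separates them.  Posterior contrasts on a single
  metabolic parameter therefore carry honest attribution width even when
  the overall deficit is precisely estimated, and their posterior-mean
  signs fluctuate between replicate studies at small scale.  The sampler
  includes a paired $(\log H_x, \log K_x)$ proposal specifically so this
  valley is actually explored rather than silently under-sampled.

* The cylinder-with-power-law body is rigid: weight that accrues without
  height (fat, muscle) cannot be represented; the unequal error priors are
  the compensation, and height fits are by design better than weight fits.
* The skeletal-weight mapping and the skin-to-intestinal surface ratio are
  reduced to configurable constants; absolute levels of $H$ (and to a
  lesser degree $q$) inherit that arbitrariness.
* The metabolic-activity decline is a one-parameter interpolation, not a
  measured marrow-composition curve.
* Sparse-design ages are taken as exact; age-recording error is not
  modelled.
* The sampler is a random-walk design: for much larger studies (thousands
  of persons) a gradient-based backend would mix faster; the model
  definition is backend-neutral and `build_model()$log_posterior` exposes
  the target density for external samplers.
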