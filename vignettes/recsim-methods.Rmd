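---
title: "recsim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{recsim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recsim)
```

## The question the simulator answers

Place-tailored smartphone apps that surface nearby free exercise classes
are an inexpensive candidate intervention against overweight and obesity,
but their population-level effect depends on an adoption funnel (awareness,
download, opting into notifications) that is far from complete, on early
attrition, and on whether women can physically reach a recreation center at
all. `recsim` is an agent-based simulator built to explore exactly that
question: for a synthetic population of adult women (ages 18-65) spread
over eight city wards, it simulates each woman's daily decision to attend a
recreation-center class, converts attendance into energy expenditure and
body-composition change over a multi-year horizon, and contrasts scenarios
with and without the app across a grid of baseline exercise propensities
and app-engagement levels.

The simulator is deliberately structural: its value is in orderings,
ceilings and time profiles (does higher engagement raise physical activity
and lower obesity prevalence, how hard is the accessibility ceiling, how
long do weight effects take to accrue), not in forecasting absolute
prevalence for a particular real city, which would require census
microdata and a real center registry that are outside its scope.

## Agents and the daily decision

Each agent carries demographics (age, height, income), body composition
(fat and lean mass), locations (home, drawn inside her ward; work, carried
but unused by default), transport (car access) and technology (smartphone
ownership) attributes. On every simulated day she attends at most one
class, and only if **five gates** all pass, in order:

1. **Motivation** — Bernoulli at her *baseline exercise probability*, the
   scenario knob (varied 0.10-0.50) that absorbs everything the model does
   not unpack: past experience, family constraints, health, social
   influences.
2. **Objective access** — deterministic: some center within walking reach
   of home (default 1.0 km), or within driving reach (default 8 km) if she
   has a car, holds a class today. Reach is a binary threshold with closed
   boundaries, because access acts in this model as a hard ceiling on
   participation, not a soft deterrent.
3. **Perceived access** — Bernoulli: does she know a reachable center is
   practically available to her?
4. **Class awareness** — Bernoulli: does she know a class is on today?
5. **Preparedness** — Bernoulli: does she have apparel and equipment ready?

Gates 3-5 are independent draws each day; the joint law of the underlying
psychology is unknown, and a sequential conjunction of independent gates is
the simplest structure that is interpretable, exactly analysable (the
participation probability is the product of the gate probabilities, which
the test suite verifies by Monte Carlo), and monotone in every parameter.

A consequence worth stating plainly: with independent daily draws, any
agent with objective access and non-zero gate product will eventually
attend at least once, so over five years the ever-participated fraction
converges to the objective-access fraction regardless of the baseline
probability. Real populations show persistent never-exercisers even among
those with access; reproducing that would need persistent per-agent
heterogeneity in the gates, which is deliberately out of scope here. The
package's validation metrics are therefore orderings
(daily &le; monthly &le; ever &le; access), not absolute rates.

## The app

The digital-health app changes nothing about the environment; it only
raises gate probabilities for its active users:

* **Adoption cascade.** A scenario's engagement triple
  (`p_aware`, `p_download | aware`, `p_notify | download`) thins the
  population in three sequential stages; download additionally requires a
  smartphone (ownership defaults to 80%). `engagement_cascade()` exposes
  the deterministic expected counts (rounding half away from zero at each
  stage, matching how such funnels are conventionally reported) and the
  sampled per-agent version used inside simulations.
* **Attrition.** Discontinuation is confined to the first 90 days after
  introduction: at adoption each downloader is either retained for good
  (probability `r_inf`, default 0.3) or assigned a churn day uniform on
  [0, 90]. The uniform-within-window shape is the package's choice; only
  the window and the existence of a retained core are structural
  assumptions, so both are configuration parameters.
* **Evening prompt.** Each evening the app asks active, notification-opted
  users which class they want tomorrow, provided some reachable center
  holds one; prompted agents use the app-modified probabilities in gates
  3-5 the next day (knowledge of schedules, reminders about equipment).
* **Geofence.** If any center lies within 0.5 miles (0.804672 km, closed
  boundary) of the home, the app notifies the user, raising the
  perceived-access gate (gate 3) to its app-modified value that day. The
  geofence is evaluated once daily at the home location; there is no
  within-day movement model.

The app-modified gate probabilities are constrained to be at least their
unmodified counterparts, so introducing the app can never lower anyone's
participation probability — an invariant the test suite checks under
common random numbers.

## Body-weight dynamics

Weight is tracked as two compartments, fat mass $F$ and lean mass $L$,
updated once per simulated day from the net energy balance

$$\Delta E \;=\; I \;-\; \mathrm{TEE}(L) \;-\; E_{\mathrm{ex}}(F+L),$$

with

* intake $I$ **calibrated once** so that $\Delta E = 0$ at the initial
  composition with zero participation — weight is stationary absent the
  intervention, and compensatory eating is excluded by construction
  (intake never changes);
* maintenance expenditure $\mathrm{TEE} = \mathrm{PAL}\cdot(19.7\,L + 413)$
  kcal/day, a physical-activity-level multiple (default 1.5) of a
  Cunningham-style resting metabolic rate linear in lean mass — linear in
  the model's own state variable, unlike weight-based RMR formulas;
* class energy $E_{\mathrm{ex}} = (\mathrm{METs}-1)\cdot w \cdot t/60$
  kcal for current weight $w$ (kg) and duration $t$ (minutes), using
  1 MET = 1 kcal kg$^{-1}$ h$^{-1}$; the resting MET is subtracted by
  default because resting expenditure during the class hour is already
  inside TEE (a gross mode is available by flag). Classes default to 50
  minutes at 6.5 METs.

The balance is split by the Forbes partition: the lean share is
$p = c/(c+F)$ with $c = 10.4$ kg, and each compartment changes by its
share divided by its tissue energy density ($\rho_L = 1807$,
$\rho_F = 9440$ kcal/kg). This two-compartment energy-density model is the
standard closed-form-checkable choice for multi-year weight simulation:
energy bookkeeping is exact (the suite verifies
$\rho_L \Delta L + \rho_F \Delta F = \sum \Delta E$ to 1e-6 relative over
five years), and a constant daily exercise load drives the state to the
fixed point $I = \mathrm{TEE} + E_{\mathrm{ex}}$, which the default
constants reach to well under 1 kcal/day within the five-year horizon.
Compartments are floored at 25 kg lean / 2 kg fat, with any residual
deficit discarded; the floors are physiological guard rails that no
realistic scenario activates (the bookkeeping test asserts they stay
inactive). There is no adaptive thermogenesis and no glycogen/water
compartment — refinements that matter for short-term dieting dynamics, not
for the slow exercise-driven drifts simulated here.

Initial composition splits BMI-implied weight with the Deurenberg equation
for women, $\mathrm{BF\%} = 1.2\,\mathrm{BMI} + 0.23\,\mathrm{age} - 5.4$,
clamped to a [5%, 60%] fat fraction; it is simple, female-specific and
needs only attributes the agents already have. BMI categories are disjoint
with closed lower boundaries: overweight $25 \le \mathrm{BMI} < 30$,
obesity $\mathrm{BMI} \ge 30$.

## Synthetic population and environment

No external data are required. The generator draws, per agent: ward
(multinomial in the ward shares), home uniform in the ward's rectangle of
an abstract 2 &times; 4 mosaic of 5 km &times; 5 km wards, age uniform on
18-65, height normal (1.63 m &plusmn; 0.07), initial BMI lognormal, income
lognormal, and Bernoulli car/smartphone flags. Only distances enter the
mechanism, so the planar mosaic loses nothing relative to real geography
except realistic spatial clustering. Choices a user should be conscious
of:

* **Initial BMI distribution** (default `meanlog = log(30.5)`,
  `sdlog = 0.18`) entirely determines initial overweight/obesity
  prevalence; it is an explicit scenario input, not an estimate.
* **Gate defaults** of 0.55 each place the no-app daily participation rate
  near 2% at a 25% baseline probability — the calibration point used for
  structural validation; app-modified gates default to 0.85.
* **Centers per ward** default to (3, 3, 3, 4, 3, 6, 1, 2): heterogeneous
  on purpose, giving one well-served ward (6) and one underserved ward (7)
  so ward-level disparity analyses have something to show. Work-place
  accessibility is not modeled; home-based access is the proxy.
* Income and work location are carried on each agent but have no
  behavioural mechanism by default.

What the generator does **not** emulate: household co-residence and social
networks, income-access correlation, realistic age-BMI structure,
within-city commuting. Tests passing on these synthetic populations
establish the simulator's internal contracts (conservation, monotonicity,
ceilings, pairing), not fidelity to any real city's surveillance data.

## Experiments, pairing and uncertainty

An experiment runs a scenario `replicates` times (default 10) over
`horizon_years` (default 5). Years are 364 days — 52 exact weeks — so
minutes-per-week aggregation is exact and every year starts on a Monday;
classes default to weekdays. Each replicate re-generates population and
environment from a replicate seed derived from the master seed.

All randomness is organised for **common random numbers**: every draw
(population, environment, adoption and churn uniforms, and the four gate
uniforms each day) comes from a stream indexed only by the replicate seed
and a stream/day counter, never by scenario parameters, and the adoption
uniforms are drawn even in no-app scenarios. Consequently two scenarios
sharing a master seed see identical populations and identical daily
uniforms: a zero-awareness app scenario is bit-identical to the no-app
scenario, raising any engagement component enlarges the participating set
pointwise (agent by agent, day by day), and app-vs-no-app contrasts can be
evaluated as paired per-replicate differences. The per-day reseeding
design gives these guarantees with O(agents) memory rather than storing an
agents &times; days &times; gates array of uniforms.

Uncertainty is summarised across replicates only: means with 95%
t-intervals (df = replicates &minus; 1), undefined (reported `NA`) for a
single replicate. A contrast is called statistically significant when the
t-interval of the paired per-replicate difference excludes zero — a
pragmatic criterion chosen because the replicate is the natural unit of
Monte-Carlo error here.

Reported outcomes per scenario: percent ever exercising, population mean
class PA minutes/week, overweight and obesity prevalence (disjoint), mean
BMI, mean BMI among obese women, mean daily and monthly participation
rates, all overall, per ward, and as yearly time series.

## Numerical and edge-case conventions

* Distance thresholds, geofence membership and BMI category boundaries are
  all closed (&le; / &ge;).
* Expected-mode cascade counts round half away from zero at each stage.
* When several reachable centers hold a class the same day, the agent
  attends the nearest one (precomputed per weekday); its duration and
  intensity define her session.
* Expected-mode adoption inside a simulation realises the deterministic
  stage counts by ranking the shared adoption uniforms, preserving both
  the exact counts and the nesting across engagement levels.
* Ties in nearest-center selection resolve to the lowest center index.
* An environment in which no agent has objective access triggers a warning
  and runs to completion with all-zero participation.
* A churned user never re-adopts; there is no re-engagement mechanism.

## Problem sizes

The package's own test suite and the acceptance script run at desk scale:
10,000 agents, 10 replicates, 5 simulated years for the scenario-grid
properties (a few minutes on one core), and hundreds to a few thousand
agents for unit-level checks. The full 167,356-agent population is
supported by the same code path — memory and time scale linearly in
agents — and all prevalence- and rate-type metrics are population-size
free, which is what makes the desk scale meaningful.

## Worked example

```{r example, eval = FALSE}
library(recsim)

no_app <- scenario_config(
  population = population_spec(n_agents = 10000),
  baseline_exercise_prob = 0.25,
  horizon_years = 5, replicates = 10, seed = 2024)

with_app <- no_app
with_app$engagement <- engagement_triple(0.75, 0.75, 0.75)

ref <- run_experiment(no_app)
app <- run_experiment(with_app)
delta_summary(app, ref)   # paired contrasts with 95% CIs
```

## Known limitations

* No social-network influence, habit formation, capacity limits, transit
  networks, web-based classes, or re-adoption after churn.
* Intake is fixed at its calibrated value: no compensatory eating and no
  dietary intervention.
* The iid daily gates imply the ever-participation ceiling is reached at
  any positive baseline probability over long horizons (see above).
* Absolute prevalence outputs are only as meaningful as the user-supplied
  initial BMI distribution and environment parameters.
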