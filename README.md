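# recsim

Agent-based simulation of recreation-center exercise-class participation,
body-weight dynamics, and a place-tailored digital-health app intervention.

`recsim` is aimed at public-health modellers who want to stress-test a
location-aware exercise app *before* it is built: given a synthetic
population of adult women (18-65) spread over eight city wards, it
simulates each woman's daily decision to attend a free recreation-center
class, converts attendance into fat/lean-mass change through an
energy-balance model over a multi-year horizon, and contrasts scenarios
with and without the app across a grid of baseline exercise propensities
and app-engagement levels — all under common random numbers, so the
intervention contrasts are paired and low-variance.

## The model in brief

**Participation.** Agent *i* attends a class on day *t* iff five gates all
pass:

1. Bernoulli(*p*<sub>base</sub>) — baseline motivation (scenario knob, 0.10-0.50);
2. objective access — a center within 1.0 km walk of home, or 8 km if she
   has a car, holds a class today (binary threshold, hard ceiling);
3. Bernoulli(*p*<sub>perc</sub>) — perceived accessibility;
4. Bernoulli(*p*<sub>aware</sub>) — awareness of today's class;
5. Bernoulli(*p*<sub>prep</sub>) — preparedness (apparel/equipment).

The app adopts users through a three-stage cascade (aware → download →
notifications; download requires a smartphone, ownership 80%), loses them
through a 90-day attrition window with a retained core *r*<sub>∞</sub>,
and for active users raises gates 3-5 to app-modified values via evening
class prompts and a 0.5-mile home geofence.

**Weight.** Two compartments with a Forbes partition (lean share
*p* = *c*/(*c*+*F*), *c* = 10.4 kg; energy densities 1807 / 9440 kcal/kg),
maintenance expenditure TEE = PAL·(19.7·*L* + 413) kcal/day, class energy
(METs−1)·weight·minutes/60 at 6.5 METs for 50 minutes, and intake
calibrated once so weight is stationary absent the intervention (no
compensatory eating).

**Experiments.** Replicated runs (default 10 × 5 years, 364-day years)
report percent ever exercising, PA minutes/week, overweight/obesity
prevalence (disjoint, BMI ≥ 30 obese), mean BMI, overall, per ward, and
yearly — each with a 95% t-interval across replicates, plus paired
app-vs-no-app deltas.

See `vignettes/recsim-methods.Rmd` for the full account, including every
default and its rationale.

## Worked example

```r
library(recsim)

no_app <- scenario_config(
  population = population_spec(n_agents = 10000),
  baseline_exercise_prob = 0.25,
  horizon_years = 5, replicates = 10, seed = 2024)

with_app <- no_app
with_app$engagement <- engagement_triple(0.75, 0.75, 0.75)

ref <- run_experiment(no_app)
app <- run_experiment(with_app)
app
#> Scenario: baseline exercise prob 0.25, app engagement 0.75-0.75-0.75, 10 replicate(s), 5 year(s)
#>             metric   mean  ci_lo  ci_hi
#> 1:        pct_ever 69.024 68.507 69.541
#> 2:     pa_min_week  9.224  9.169  9.278
#> 3: overweight_prev 33.645 33.407 33.883
#> 4:    obesity_prev 52.091 51.775 52.407
#> 5:        mean_bmi 30.778 30.746 30.810
#> 6:  mean_bmi_obese 34.962 34.931 34.993
#> 7:      daily_rate  2.635  2.620  2.651
#> 8:    monthly_rate 44.003 43.717 44.289
#> 9:      access_pct 69.024 68.507 69.541

delta_summary(app, ref)
#>             metric delta_mean   ci_lo   ci_hi significant
#> 1:        pct_ever     0.0000  0.0000  0.0000       FALSE
#> 2:     pa_min_week     2.0449  2.0011  2.0888        TRUE
#> 3: overweight_prev     0.1220  0.0734  0.1706        TRUE
#> 4:    obesity_prev    -0.2750 -0.3118 -0.2382        TRUE
#> ...
```

Reading this: at 75-75-75 engagement the app adds about 2.0 class minutes
per week on average and lowers obesity prevalence by about 0.28 percentage
points after five years (paired CIs excluding zero), while the percent
ever exercising cannot move — it already sits at the objective-access
ceiling (`access_pct`), which the app cannot raise. Overweight prevalence
*increases* slightly because women leaving the obese category land in it.

Scenarios can also be declared in YAML (`read_scenario_config()`) and run
from a shell via the thin CLI in `inst/cli/simulate.R`
(`run` / `experiment` / `grid` / `validate` subcommands).

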