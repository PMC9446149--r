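# shared fixture builders: small scenarios that run in well under a second

small_pop <- function(n = 500L, seed = 11L, ...) {
  population_spec(n_agents = n, seed = seed, ...)
}

small_config <- function(n = 500L, years = 1, reps = 1L, seed = 11L,
                         engagement = NULL, baseline = 0.25, ...) {
  scenario_config(population = small_pop(n),
                  engagement = engagement,
                  baseline_exercise_prob = baseline,
                  horizon_years = years, replicates = reps,
                  seed = seed, ...)
}

# an environment where every agent can reach a class every day
saturated_config <- function(n = 200L, years = 1, seed = 3L, ...) {
  scenario_config(
    population = small_pop(n),
    environment = environment_spec(walk_reach_km = 50, drive_reach_km = 50,
                                   class_weekdays = 1:7),
    gates = gate_params(1, 1, 1, 1, 1, 1),
    baseline_exercise_prob = 1,
    horizon_years = years, replicates = 1L, seed = seed, ...)
}

# hand-built run object for pure counting checks
fake_run <- function(daily, monthly, ever, n, n_days) {
  structure(list(agents = data.table::data.table(ever = ever),
                 daily_participants = daily, monthly_any = monthly,
                 meta = list(n = n, n_days = n_days)),
            class = "recsim_run")
}
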