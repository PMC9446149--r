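#' Scenario configuration
#'
#' Full parameterisation of one experiment cell: population, environment,
#' behavioural gates, metabolic constants, the app engagement triple (or
#' `NULL` for a no-app scenario), attrition, the baseline exercise
#' probability, horizon, replicate count and master seed. Scenarios sharing
#' a master seed are run under common random numbers: identical populations,
#' environments and gate uniforms, so intervention contrasts are paired.
#'
#' @param population a [population_spec()].
#' @param environment an [environment_spec()].
#' @param gates a [gate_params()].
#' @param metabolic a [metabolic_params()].
#' @param engagement an [engagement_triple()] or `NULL` (no app).
#' @param attrition an [attrition_params()].
#' @param baseline_exercise_prob per-day probability of wanting to exercise,
#'   varied 0.10-0.50 across the scenario grid.
#' @param horizon_years simulated horizon; years are 364 days (52 exact
#'   weeks) so weekly aggregation is exact.
#' @param replicates number of replicate runs.
#' @param seed master integer seed.
#' @param app_intro_day 0-based day the app is introduced.
#' @param engagement_mode `"sampled"` (Bernoulli thinning) or `"expected"`
#'   (deterministic stage counts, filled by ranking the shared adoption
#'   uniforms).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(population = population_spec(),
                            environment = environment_spec(),
                            gates = gate_params(),
                            metabolic = metabolic_params(),
                            engagement = NULL,
                            attrition = attrition_params(),
                            baseline_exercise_prob = 0.25,
                            horizon_years = 5,
                            replicates = 10L,
                            seed = 1L,
                            app_intro_day = 0L,
                            engagement_mode = c("sampled", "expected")) {
  if (baseline_exercise_prob < 0 || baseline_exercise_prob > 1) {
    stop_config("baseline_exercise_prob", "must lie in [0,1]")
  }
  if (horizon_years <= 0) stop_config("horizon_years", "must be positive")
  if (replicates < 1L) stop_config("replicates", "must be at least 1")
  if (!is.null(engagement) && !inherits(engagement, "engagement_triple")) {
    stop_config("engagement", "must be an engagement_triple() or NULL")
  }
  structure(list(population = population, environment = environment,
                 gates = gates, metabolic = metabolic,
                 engagement = engagement, attrition = attrition,
                 baseline_exercise_prob = baseline_exercise_prob,
                 horizon_years = horizon_years,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 app_intro_day = as.integer(app_intro_day),
                 engagement_mode = match.arg(engagement_mode)),
            class = "scenario_config")
}

# per-agent adoption states under common random numbers; "expected" mode
# realises the deterministic cascade counts by ranking the shared uniforms
draw_app_states <- function(agents, config, u) {
  if (is.null(config$engagement) || config$engagement_mode == "sampled") {
    return(sample_app_states(agents, config$engagement, config$attrition, u))
  }
  n <- nrow(agents)
  triple <- config$engagement
  take_smallest <- function(candidates, u_col, k) {
    out <- rep(FALSE, n)
    idx <- which(candidates)
    if (length(idx) == 0L || k <= 0) return(out)
    k <- min(k, length(idx))
    out[idx[order(u_col[idx])[seq_len(k)]]] <- TRUE
    out
  }
  aware <- take_smallest(rep(TRUE, n), u[, 1L],
                         round_half_up(triple$p_aware * n))
  downloaded <- take_smallest(aware & agents$has_smartphone, u[, 2L],
                              round_half_up(triple$p_download * sum(aware)))
  notifications_on <- take_smallest(downloaded, u[, 3L],
                                    round_half_up(triple$p_notify *
                                                    sum(downloaded)))
  churns <- downloaded & u[, 4L] >= config$attrition$r_inf
  churn_day <- rep(NA_real_, n)
  churn_day[churns] <- u[churns, 5L] * config$attrition$window_days
  data.table(aware = aware, downloaded = downloaded,
             notifications_on = notifications_on, churn_day = churn_day)
}

#' Run one replicate simulation
#'
#' Executes the daily loop over the full horizon: app evening prompts
#' (decided the previous evening) and geofence notifications, the five-gate
#' participation decision, class sessions at the nearest reachable center
#' with a class that weekday, and the metabolic update. Intake is calibrated
#' once so weight is stationary at zero participation. Deterministic for a
#' fixed `replicate_seed`; every random draw (population, environment,
#' adoption, gate uniforms) depends only on the replicate seed and a stream
#' index, never on scenario parameters, so scenarios sharing a seed are
#' pointwise comparable.
#'
#' @param config a [scenario_config()].
#' @param replicate_seed integer seed for this replicate (defaults to the
#'   config master seed).
#' @return an object of class `recsim_run`: list with `agents` (per-agent
#'   outcome table), `daily_participants` (integer vector, one per day),
#'   `monthly_any` (participants with >= 1 class per 30-day window),
#'   `yearly` (end-of-year time series) and `meta`.
#' @export
run_simulation <- function(config, replicate_seed = config$seed) {
  pspec <- config$population
  pspec$seed <- as.integer(replicate_seed)
  agents <- generate_population(pspec, config$baseline_exercise_prob)
  n <- nrow(agents)
  centers <- build_environment(config$environment,
                               seed = derive_seed(replicate_seed, 1L))
  acc <- compute_access(agents, centers, config$environment)
  if (!any(acc$access)) {
    warning("no agent has objective access to any recreation center; ",
            "participation will be zero", call. = FALSE)
  }

  # adoption/churn uniforms are always drawn, even for no-app scenarios,
  # so downstream streams stay aligned across scenarios (common random
  # numbers; the (0,.,.) triple is then bit-identical to no-app)
  set.seed(derive_seed(replicate_seed, 2L))
  u_app <- matrix(runif(5L * n), n, 5L)
  states <- draw_app_states(agents, config, u_app)

  params <- config$metabolic
  gates <- config$gates
  baseline <- config$baseline_exercise_prob
  intro <- config$app_intro_day
  fat <- agents$fat_mass
  lean <- agents$lean_mass
  intake <- calibrate_intake(lean, params)
  fat0 <- fat; lean0 <- lean

  # per-weekday session duration / intensity from the chosen center
  dur_dow <- matrix(0, n, 7)
  mets_dow <- matrix(0, n, 7)
  has_choice <- acc$chosen > 0L
  dur_dow[has_choice] <- centers$class_duration[acc$chosen[has_choice]]
  mets_dow[has_choice] <- centers$class_mets[acc$chosen[has_choice]]

  n_days <- round(config$horizon_years * 364)
  notif <- states$downloaded & states$notifications_on
  churn <- states$churn_day
  geof <- acc$geofenced

  n_classes <- integer(n)
  minutes_total <- numeric(n)
  minutes_year <- numeric(n)
  daily_participants <- integer(n_days)
  monthly_any <- integer(n_days %/% 30L)
  win_any <- rep(FALSE, n)
  win_i <- 0L
  yearly <- vector("list", max(1L, n_days %/% 364L))

  app_active_on <- function(d) {
    if (is.null(config$engagement)) return(rep(FALSE, n))
    states$downloaded & d >= intro & (is.na(churn) | (d - intro) < churn)
  }

  for (d in 0:(n_days - 1L)) {
    dow <- d %% 7L + 1L
    # evening prompt was decided yesterday, by yesterday's active users
    prompted <- if (d > 0L) {
      evening_prompt(app_active_on(d - 1L), notif, acc$by_dow[, dow])
    } else rep(FALSE, n)
    active_today <- app_active_on(d)
    geo_notified <- active_today & notif & geof

    set.seed(derive_seed(replicate_seed, 10L + d))
    u <- matrix(runif(4L * n), n, 4L)
    part <- daily_decision(baseline, acc$by_dow[, dow], gates,
                           prompted = prompted,
                           geofence_notified = geo_notified, u = u)

    minutes <- dur_dow[, dow] * part
    weight <- fat + lean
    ex <- numeric(n)
    if (any(part)) {
      ex[part] <- exercise_kcal(weight[part], mets_dow[part, dow],
                                minutes[part], params)
    }
    net <- intake - total_expenditure(lean, params) - ex
    upd <- update_composition(fat, lean, net, params)
    fat <- upd$fat_mass
    lean <- upd$lean_mass

    daily_participants[d + 1L] <- sum(part)
    n_classes <- n_classes + part
    minutes_total <- minutes_total + minutes
    minutes_year <- minutes_year + minutes
    win_any <- win_any | part
    if ((d + 1L) %% 30L == 0L) {
      win_i <- win_i + 1L
      monthly_any[win_i] <- sum(win_any)
      win_any <- rep(FALSE, n)
    }
    if ((d + 1L) %% 364L == 0L) {
      bc <- bmi_and_category(fat, lean, agents$height)
      yearly[[(d + 1L) %/% 364L]] <- data.table(
        year = (d + 1L) %/% 364L,
        pct_ever = 100 * mean(n_classes > 0L),
        pa_min_week = mean(minutes_year) / 52,
        mean_bmi = mean(bc$bmi),
        overweight_prev = 100 * mean(bc$category == "overweight"),
        obesity_prev = 100 * mean(bc$category == "obese"))
      minutes_year <- numeric(n)
    }
  }

  bc0 <- bmi_and_category(fat0, lean0, agents$height)
  bc <- bmi_and_category(fat, lean, agents$height)
  out <- data.table(id = agents$id, ward_id = agents$ward_id,
                    has_car = agents$has_car,
                    has_smartphone = agents$has_smartphone,
                    access = acc$access,
                    app_aware = states$aware,
                    app_downloaded = states$downloaded,
                    app_notifications = states$notifications_on,
                    ever = n_classes > 0L, n_classes = n_classes,
                    minutes_total = minutes_total,
                    bmi0 = bc0$bmi, bmi = bc$bmi, category = bc$category,
                    fat_mass = fat, lean_mass = lean)
  structure(list(agents = out,
                 daily_participants = daily_participants,
                 monthly_any = monthly_any,
                 yearly = rbindlist(yearly[!vapply(yearly, is.null,
                                                   logical(1))]),
                 meta = list(n = n, n_days = n_days,
                             replicate_seed = as.integer(replicate_seed))),
            class = "recsim_run")
}

#' Participation rates of a run
#'
#' `daily_rate` is the mean over days of the percentage of the population
#' participating that day; `monthly_rate` the mean over consecutive 30-day
#' windows of the percentage participating at least once in the window;
#' `ever_rate` the percentage participating at least once over the horizon.
#' By construction `daily <= monthly <= ever`.
#'
#' @param run a `recsim_run` from [run_simulation()].
#' @return named numeric vector (percent): `daily_rate`, `monthly_rate`,
#'   `ever_rate`.
#' @export
participation_metrics <- function(run) {
  if (run$meta$n_days < 30) {
    stop("need at least 30 simulated days", call. = FALSE)
  }
  n <- run$meta$n
  c(daily_rate = 100 * mean(run$daily_participants / n),
    monthly_rate = 100 * mean(run$monthly_any / n),
    ever_rate = 100 * mean(run$agents$ever))
}

# one summary row (population level) for a finished run
summarize_run <- function(run) {
  a <- run$agents
  pm <- participation_metrics(run)
  obese <- a$category == "obese"
  data.table(pct_ever = 100 * mean(a$ever),
             pa_min_week = mean(weekly_pa_minutes(a$minutes_total,
                                                  run$meta$n_days)),
             overweight_prev = 100 * mean(a$category == "overweight"),
             obesity_prev = 100 * mean(obese),
             mean_bmi = mean(a$bmi),
             mean_bmi_obese = if (any(obese)) mean(a$bmi[obese]) else NA_real_,
             daily_rate = pm[["daily_rate"]],
             monthly_rate = pm[["monthly_rate"]],
             access_pct = 100 * mean(a$access))
}

#' Per-ward outcome summary of a run
#'
#' Groups the per-agent outcomes of one run by ward.
#'
#' @param run a `recsim_run`.
#' @return a `data.table` with one row per ward: agent count, percent ever
#'   exercised, mean PA minutes/week, overweight/obesity prevalence and mean
#'   BMI.
#' @export
ward_summary <- function(run) {
  n_days <- run$meta$n_days
  run$agents[, .(
    n = as.numeric(.N),
    pct_ever = 100 * mean(ever),
    pa_min_week = mean(weekly_pa_minutes(minutes_total, n_days)),
    overweight_prev = 100 * mean(category == "overweight"),
    obesity_prev = 100 * mean(category == "obese"),
    mean_bmi = mean(bmi),
    access_pct = 100 * mean(access)
  ), keyby = ward_id]
}

#' Run a replicated experiment for one scenario
#'
#' Runs `config$replicates` independent replicate simulations (replicate
#' seeds derived from the master seed) and aggregates every outcome with its
#' mean and 95% t-interval across replicates (df = replicates - 1). With a
#' single replicate the interval is reported as `NA`. Two scenarios sharing
#' a master seed use identical replicate seeds and are therefore paired for
#' [delta_summary()].
#'
#' @param config a [scenario_config()].
#' @param progress emit per-replicate progress messages to stderr.
#' @return an object of class `outcome_summary`: list with `summary`
#'   (metric, mean, ci_lo, ci_hi), `replicates` (per-replicate metric
#'   table), `wards` (per-ward means with CIs), `wards_replicates`,
#'   `timeseries` (yearly means with CIs) and the `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  reps <- vector("list", config$replicates)
  wards <- vector("list", config$replicates)
  years <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    seed_r <- derive_seed(config$seed, 100000L + r)
    if (progress) {
      message(sprintf("replicate %d/%d (seed %d)",
                      r, config$replicates, seed_r))
    }
    run <- run_simulation(config, replicate_seed = seed_r)
    reps[[r]] <- cbind(data.table(replicate = r, seed = seed_r),
                       summarize_run(run))
    wards[[r]] <- cbind(data.table(replicate = r), ward_summary(run))
    years[[r]] <- cbind(data.table(replicate = r), run$yearly)
  }
  replicates <- rbindlist(reps)
  wards_replicates <- rbindlist(wards)
  years_replicates <- rbindlist(years)

  metric_cols <- setdiff(names(replicates), c("replicate", "seed"))
  summary <- rbindlist(lapply(metric_cols, function(mname) {
    ci <- ci_t(replicates[[mname]])
    data.table(metric = mname, mean = ci[["mean"]],
               ci_lo = ci[["ci_lo"]], ci_hi = ci[["ci_hi"]])
  }))

  agg_ci <- function(dt, by) {
    if (nrow(dt) == 0L || !by %in% names(dt)) {
      # horizons shorter than a year produce no end-of-year snapshots
      return(data.table(metric = character(), mean = numeric(),
                        ci_lo = numeric(), ci_hi = numeric()))
    }
    vals <- setdiff(names(dt), c("replicate", by))
    long <- melt(dt, id.vars = c("replicate", by),
                 measure.vars = vals, variable.name = "metric",
                 variable.factor = FALSE)
    long[, {
      ci <- ci_t(value)
      .(mean = ci[["mean"]], ci_lo = ci[["ci_lo"]], ci_hi = ci[["ci_hi"]])
    }, keyby = c(by, "metric")]
  }

  structure(list(summary = summary, replicates = replicates,
                 wards = agg_ci(wards_replicates, "ward_id"),
                 wards_replicates = wards_replicates,
                 timeseries = agg_ci(years_replicates, "year"),
                 config = config),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  eng <- x$config$engagement
  cat(sprintf(
    "Scenario: baseline exercise prob %.2f, %s, %d replicate(s), %g year(s)\n",
    x$config$baseline_exercise_prob,
    if (is.null(eng)) "no app" else
      sprintf("app engagement %.4g-%.4g-%.4g",
              eng$p_aware, eng$p_download, eng$p_notify),
    x$config$replicates, x$config$horizon_years))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Paired scenario contrast (app vs no-app)
#'
#' Differences of every population metric between two experiments run under
#' common random numbers (same master seed, same replicate count): the
#' per-replicate differences are paired, and a 95% t-interval of the paired
#' difference is reported; the difference is flagged significant when the
#' interval excludes zero.
#'
#' @param x,ref `outcome_summary` objects; `ref` is the comparator (e.g.
#'   the no-app scenario).
#' @return a `data.table` with `metric`, `delta_mean`, `ci_lo`, `ci_hi`,
#'   `significant`.
#' @export
delta_summary <- function(x, ref) {
  stopifnot(inherits(x, "outcome_summary"), inherits(ref, "outcome_summary"))
  if (nrow(x$replicates) != nrow(ref$replicates)) {
    stop("experiments must have the same number of replicates", call. = FALSE)
  }
  if (!identical(x$replicates$seed, ref$replicates$seed)) {
    stop("experiments are not paired: replicate seeds differ ",
         "(use the same master seed)", call. = FALSE)
  }
  metric_cols <- setdiff(names(x$replicates), c("replicate", "seed"))
  rbindlist(lapply(metric_cols, function(mname) {
    diff <- x$replicates[[mname]] - ref$replicates[[mname]]
    ci <- ci_t(diff)
    data.table(metric = mname, delta_mean = ci[["mean"]],
               ci_lo = ci[["ci_lo"]], ci_hi = ci[["ci_hi"]],
               significant = !is.na(ci[["ci_lo"]]) &&
                 (ci[["ci_lo"]] > 0 || ci[["ci_hi"]] < 0))
  }))
}

#' Write experiment outputs as CSV
#'
#' Writes `summary.csv` (one row per metric with mean and CI), `wards.csv`
#' and `timeseries.csv` into `dir`.
#'
#' @param x an `outcome_summary`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outcome_summary <- function(x, dir) {
  stopifnot(inherits(x, "outcome_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(x$summary, file.path(dir, "summary.csv"))
  fwrite(x$wards, file.path(dir, "wards.csv"))
  fwrite(x$timeseries, file.path(dir, "timeseries.csv"))
  invisible(dir)
}
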