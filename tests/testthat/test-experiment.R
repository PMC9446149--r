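test_that("null scenario has zero participation and stationary weight", {
  run <- run_simulation(small_config(n = 300L, baseline = 0))
  expect_equal(sum(run$daily_participants), 0L)
  expect_false(any(run$agents$ever))
  expect_equal(run$agents$bmi, run$agents$bmi0, tolerance = 1e-12)
})

test_that("runs are deterministic for a fixed replicate seed", {
  cfg <- small_config(n = 300L,
                      engagement = engagement_triple(0.5, 0.5, 0.5))
  a <- run_simulation(cfg, replicate_seed = 77L)
  b <- run_simulation(cfg, replicate_seed = 77L)
  expect_identical(a$agents, b$agents)
  expect_identical(a$daily_participants, b$daily_participants)
  expect_false(identical(
    a$agents, run_simulation(cfg, replicate_seed = 78L)$agents))
})

test_that("a saturated scenario reaches 100% participation in the first week", {
  run <- run_simulation(saturated_config(n = 200L))
  expect_equal(run$daily_participants[1:7], rep(200L, 7))
  expect_equal(participation_metrics(run),
               c(daily_rate = 100, monthly_rate = 100, ever_rate = 100))
  # every week is 7 classes of 50 minutes
  expect_equal(unique(weekly_pa_minutes(run$agents$minutes_total, 364)), 350)
})

test_that("a ward without centers or car access never participates", {
  cfg <- scenario_config(
    population = population_spec(n_agents = 600L,
                                 car_ownership = rep(0, 8), seed = 19L),
    environment = environment_spec(centers_per_ward = c(4, 0, 0, 0, 0, 0, 0, 0),
                                   walk_reach_km = 2, drive_reach_km = 2),
    baseline_exercise_prob = 0.5, horizon_years = 1,
    replicates = 1L, seed = 19L)
  run <- run_simulation(cfg)
  ws <- ward_summary(run)
  expect_equal(ws[ward_id == 8L]$pct_ever, 0)
  expect_equal(ws[ward_id == 8L]$access_pct, 0)
  # and the ceiling holds ward by ward
  expect_true(all(ws$pct_ever <= ws$access_pct))
})

test_that("an infeasible environment warns but still runs", {
  cfg <- scenario_config(
    population = population_spec(n_agents = 50L, seed = 2L),
    environment = environment_spec(centers_per_ward = rep(0L, 8)),
    horizon_years = 0.25, replicates = 1L, seed = 2L)
  expect_warning(run <- run_simulation(cfg), "objective access")
  expect_equal(sum(run$daily_participants), 0L)
})

test_that("participation metrics count days, windows and agents", {
  # one agent of 100 attends exactly once in 90 days
  daily <- integer(90); daily[40] <- 1L
  monthly <- c(0L, 1L, 0L)
  run <- fake_run(daily, monthly, ever = c(TRUE, rep(FALSE, 99)),
                  n = 100L, n_days = 90L)
  pm <- participation_metrics(run)
  expect_equal(pm[["daily_rate"]], 100 * (1 / 100) / 90)
  expect_equal(pm[["monthly_rate"]], 100 * mean(monthly / 100))
  expect_equal(pm[["ever_rate"]], 1)
  expect_true(pm[["daily_rate"]] <= pm[["monthly_rate"]] &&
                pm[["monthly_rate"]] <= pm[["ever_rate"]])
})

test_that("replicate aggregation reports t-intervals, degenerate cases included", {
  cfg <- small_config(n = 200L, years = 0.5, reps = 1L)
  one <- run_experiment(cfg)
  expect_true(all(is.na(one$summary$ci_lo)))  # undefined CI at R = 1
  cfg$replicates <- 3L
  three <- run_experiment(cfg)
  expect_equal(nrow(three$replicates), 3L)
  expect_true(all(three$summary$ci_lo <= three$summary$mean &
                    three$summary$mean <= three$summary$ci_hi, na.rm = TRUE))
  # a scenario against itself: zero delta with zero-width interval
  d <- delta_summary(three, three)
  expect_equal(d$delta_mean, rep(0, nrow(d)))
  expect_equal(d$ci_lo, rep(0, nrow(d)))
  expect_false(any(d$significant))
  # unpaired comparisons are refused
  other <- run_experiment(small_config(n = 200L, years = 0.5, reps = 3L,
                                       seed = 99L))
  expect_error(delta_summary(three, other), "paired")
})

test_that("scenario YAML round-trips and rejects unknown keys", {
  cfg <- scenario_config(
    population = population_spec(n_agents = 1000L, seed = 5L),
    engagement = engagement_triple(0.5, 0.5823, 0.55),
    baseline_exercise_prob = 0.1, horizon_years = 2,
    replicates = 4L, seed = 31L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$engagement$p_download, 0.5823)
  expect_equal(back$baseline_exercise_prob, 0.1)
  expect_equal(back$population$n_agents, 1000L)
  expect_equal(back$environment$class_weekdays, cfg$environment$class_weekdays)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("baseline_exercise_probability: 0.2", bad)
  expect_error(read_scenario_config(bad), "recognised")
})

test_that("experiment outputs are written as the three CSV files", {
  out <- run_experiment(small_config(n = 150L, years = 0.5, reps = 2L))
  dir <- withr::local_tempdir()
  write_outcome_summary(out, dir)
  expect_true(all(file.exists(file.path(
    dir, c("summary.csv", "wards.csv", "timeseries.csv")))))
  s <- data.table::fread(file.path(dir, "summary.csv"))
  expect_equal(names(s), c("metric", "mean", "ci_lo", "ci_hi"))
})

test_that("expected-mode adoption realises the deterministic stage counts", {
  cfg <- small_config(n = 2000L,
                      engagement = engagement_triple(0.5, 1, 0.5),
                      engagement_mode = "expected")
  # phone owners cap the download stage: counts still deterministic
  run <- run_simulation(cfg, 55L)
  a <- run$agents
  expect_equal(sum(a$app_aware), 1000)
  expect_equal(sum(a$app_downloaded), sum(a$app_aware & a$has_smartphone))
  expect_equal(sum(a$app_notifications),
               floor(0.5 * sum(a$app_downloaded) + 0.5))
})

test_that("the shipped example scenario config parses", {
  path <- system.file("extdata", "example-scenario.yaml", package = "recsim")
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$engagement$p_download, 0.5823)
  expect_equal(cfg$environment$centers_per_ward[6], 6L)
  expect_equal(cfg$replicates, 10L)
})
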