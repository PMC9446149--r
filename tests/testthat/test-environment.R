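test_that("environment build places the configured number of centers per ward", {
  spec <- environment_spec(centers_per_ward = c(3, 2, 4, 3, 2, 6, 1, 2))
  centers <- build_environment(spec, seed = 4L)
  expect_equal(nrow(centers), 23L)
  expect_equal(as.integer(table(factor(centers$ward_id, levels = 1:8))),
               c(3L, 2L, 4L, 3L, 2L, 6L, 1L, 2L))
  expect_identical(centers, build_environment(spec, seed = 4L))
  wb <- ward_bounds()
  expect_true(all(centers$x_km >= wb$xmin[centers$ward_id] &
                    centers$x_km <= wb$xmax[centers$ward_id]))
})

test_that("class availability follows the weekday schedule (day 0 = Monday)", {
  spec <- environment_spec(class_weekdays = c(1, 3, 5))  # Mon, Wed, Fri
  centers <- build_environment(spec, seed = 1L)
  expect_false(any(class_available(centers, day = 1)))   # Tuesday
  expect_true(all(class_available(centers, day = 2)))    # Wednesday
  expect_true(all(class_available(centers, day = 7)))    # next Monday
  daily <- build_environment(environment_spec(class_weekdays = 1:7), seed = 1L)
  for (d in 0:6) expect_true(all(class_available(daily, d)))
})

test_that("geofence uses a closed boundary at 0.5 miles = 0.804672 km", {
  centers <- data.table::data.table(
    id = 1:3, ward_id = 1L,
    x_km = c(0.804672, 0.9, 5), y_km = 0,
    schedule = "1111100", class_duration = 50, class_mets = 6.5)
  hit <- centers_within_geofence(0, 0, centers, radius_miles = 0.5)
  expect_equal(hit$id, 1L)  # exactly on the boundary is included
  none <- centers_within_geofence(0, 10, centers, radius_miles = 0.5)
  expect_equal(nrow(none), 0L)
  # membership grows monotonically with the radius
  sizes <- vapply(c(0.25, 0.5, 1, 4),
                  function(r) nrow(centers_within_geofence(0, 0, centers, r)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("objective access is the binary walk/drive threshold rule", {
  spec <- environment_spec(walk_reach_km = 1, drive_reach_km = 8)
  centers <- data.table::data.table(
    id = 1L, ward_id = 1L, x_km = 1, y_km = 1,
    schedule = "1111100", class_duration = 50, class_mets = 6.5)
  agent_at <- function(x, y, car) {
    data.table::data.table(id = 1L, home_x = x, home_y = y, has_car = car)
  }
  expect_true(objective_access(agent_at(1.3, 1, FALSE), centers, spec))
  expect_false(objective_access(agent_at(6, 1, FALSE), centers, spec))
  expect_true(objective_access(agent_at(6, 1, TRUE), centers, spec))   # car
  expect_false(objective_access(agent_at(15, 1, TRUE), centers, spec)) # too far
  # monotone in walk reach
  far <- environment_spec(walk_reach_km = 6, drive_reach_km = 8)
  expect_true(objective_access(agent_at(6, 1, FALSE), centers, far))
})

test_that("access precomputation matches center schedules and reach", {
  # one center in ward 1 only; carless agents in ward 8 are cut off
  spec <- environment_spec(centers_per_ward = c(1, 0, 0, 0, 0, 0, 0, 0),
                           walk_reach_km = 2, drive_reach_km = 30,
                           class_weekdays = 1:5)
  centers <- build_environment(spec, seed = 2L)
  agents <- generate_population(
    population_spec(n_agents = 400L, car_ownership = rep(0.5, 8), seed = 8L))
  acc <- compute_access(agents, centers, spec)
  far <- agents$ward_id == 8L & !agents$has_car
  expect_false(any(acc$access[far]))
  # weekday columns mirror the schedule: classes Mon-Fri only
  expect_true(all(acc$by_dow[, 6:7] == FALSE))
  expect_equal(acc$by_dow[, 1], acc$access)
  # chosen center is reachable whenever by_dow says so
  expect_true(all((acc$chosen[, 1] > 0) == acc$by_dow[, 1]))
})

test_that("center CSV round-trips including the schedule mask", {
  centers <- build_environment(environment_spec(), seed = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_centers(centers, path)
  b <- read_centers(path)
  expect_equal(as.data.frame(b), as.data.frame(centers), tolerance = 1e-12)
  expect_type(b$schedule, "character")
})
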