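test_that("expected-mode cascade reproduces the sequential rounded counts", {
  n <- 167356L
  low <- engagement_cascade(n, engagement_triple(0.25, 0.25, 0.25))
  expect_equal(low, list(n_aware = 41839, n_download = 10460, n_notify = 2615))
  high <- engagement_cascade(n, engagement_triple(0.75, 0.75, 0.75))
  expect_equal(high$n_aware, 125517)
  expect_equal(high$n_download, 94138)
  mid <- engagement_cascade(n, engagement_triple(0.50, 0.5823, 0.55))
  expect_equal(mid$n_aware, 83678)
  # full engagement is the identity chain
  expect_equal(engagement_cascade(n, engagement_triple(1, 1, 1)),
               list(n_aware = n, n_download = n, n_notify = n))
  expect_error(engagement_cascade(0, engagement_triple(1, 1, 1)), "`n`")
})

test_that("sampled-mode cascade thins sequentially and needs a smartphone to download", {
  n <- 20000L
  set.seed(12)
  phones <- runif(n) < 0.8
  casc <- engagement_cascade(n, engagement_triple(0.5, 0.5, 0.5),
                             mode = "sampled", has_smartphone = phones)
  # stage flags are nested
  expect_true(all(casc$downloaded[casc$notifications_on]))
  expect_true(all(casc$aware[casc$downloaded]))
  expect_false(any(casc$downloaded & !phones))
  # counts near the thinned expectations (download passes the 80% phone rate)
  expect_lt(abs(casc$n_aware - n * 0.5), 3 * sqrt(n * 0.5 * 0.5))
  p_dl <- 0.5 * 0.8 * 0.5
  expect_lt(abs(casc$n_download - n * p_dl), 3 * sqrt(n * p_dl * (1 - p_dl)))
  # no phones anywhere: awareness survives, downloads do not
  casc0 <- engagement_cascade(n, engagement_triple(0.5, 1, 1),
                              mode = "sampled",
                              has_smartphone = rep(FALSE, n))
  expect_gt(casc0$n_aware, 0)
  expect_equal(casc0$n_download, 0)
})

test_that("adoption states respect the cascade ordering and the churn window", {
  agents <- generate_population(small_pop(n = 5000L, seed = 14L))
  set.seed(15)
  st <- sample_app_states(agents, engagement_triple(0.75, 0.75, 0.75),
                          attrition_params(r_inf = 0.3, window_days = 90))
  expect_true(all(st$aware[st$downloaded]))
  expect_true(all(st$downloaded[st$notifications_on]))
  expect_true(all(is.na(st$churn_day) | (st$churn_day >= 0 & st$churn_day <= 90)))
  expect_true(all(is.na(st$churn_day[!st$downloaded])))
  # no-app scenario: everything off
  st0 <- sample_app_states(agents, NULL)
  expect_false(any(st0$aware | st0$downloaded | st0$notifications_on))
})

test_that("attrition never removes the retained core and stops after the window", {
  agents <- generate_population(small_pop(n = 4000L, seed = 16L))
  set.seed(17)
  keep_all <- sample_app_states(agents, engagement_triple(1, 1, 1),
                                attrition_params(r_inf = 1))
  at90 <- apply_attrition(keep_all, 90)
  expect_equal(sum(at90$active), sum(keep_all$downloaded))
  expect_error(apply_attrition(keep_all, -1), "non-negative")
})

test_that("evening prompts and geofence notifications gate correctly", {
  expect_equal(evening_prompt(c(TRUE, TRUE, FALSE, TRUE),
                              c(TRUE, FALSE, TRUE, TRUE),
                              c(TRUE, TRUE, TRUE, FALSE)),
               c(TRUE, FALSE, FALSE, FALSE))
  centers <- data.table::data.table(
    id = 1L, ward_id = 1L, x_km = 0, y_km = 0,
    schedule = "1111100", class_duration = 50, class_mets = 6.5)
  agents <- data.table::data.table(
    id = 1:2, home_x = c(0.4, 2) * 1.609344, home_y = 0)
  expect_equal(geofence_notify(agents, centers, 0.5), c(TRUE, FALSE))
  # wider radius can only add notifications
  expect_equal(geofence_notify(agents, centers, 2.5), c(TRUE, TRUE))
  expect_equal(geofence_notify(agents, centers[0], 0.5), c(FALSE, FALSE))
})
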