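#' App engagement triple
#'
#' The three sequential adoption proportions defining an app scenario: the
#' share of the population aware of the app, the share of those aware who
#' download it, and the share of downloaders who opt into push
#' notifications. Scenario grids vary all three between 25% and 75%; the
#' mid grid cell uses empirically reported rates (58.23% download, 55%
#' notifications).
#'
#' @param p_aware probability of being aware of the app.
#' @param p_download probability of downloading, conditional on awareness.
#' @param p_notify probability of opting into notifications, conditional on
#'   download.
#' @return an object of class `engagement_triple`.
#' @export
engagement_triple <- function(p_aware, p_download, p_notify) {
  t <- list(p_aware = p_aware, p_download = p_download, p_notify = p_notify)
  if (any(unlist(t) < 0 | unlist(t) > 1)) {
    stop_config("engagement_triple", "probabilities must lie in [0,1]")
  }
  structure(t, class = "engagement_triple")
}

#' Attrition parameters
#'
#' App attrition is confined to the first `window_days` after introduction:
#' at adoption each user either belongs to the retained core (probability
#' `r_inf`, never churns) or churns at a time uniform on `[0, window_days]`.
#' After the window the active fraction is constant.
#'
#' @param r_inf long-run retained fraction of downloaders.
#' @param window_days length of the attrition window, days.
#' @return an object of class `attrition_params`.
#' @export
attrition_params <- function(r_inf = 0.3, window_days = 90) {
  if (r_inf < 0 || r_inf > 1) stop_config("r_inf", "must lie in [0,1]")
  if (window_days <= 0) stop_config("window_days", "must be positive")
  structure(list(r_inf = r_inf, window_days = window_days),
            class = "attrition_params")
}

#' Engagement adoption cascade counts
#'
#' In `expected` mode the chain of counts is deterministic:
#' `n_aware = round(p_aware * n)`, `n_download = round(p_download * n_aware)`,
#' `n_notify = round(p_notify * n_download)`, rounding half away from zero.
#' In `sampled` mode each stage is a Bernoulli thinning of the previous one,
#' with download additionally restricted to smartphone owners (awareness is
#' not restricted).
#'
#' @param n population size.
#' @param triple an [engagement_triple()].
#' @param mode `"expected"` or `"sampled"`.
#' @param has_smartphone logical n, required in sampled mode.
#' @param u optional `n x 3` uniform matrix for sampled mode (common random
#'   numbers); drawn internally if `NULL`.
#' @return list with `n_aware`, `n_download`, `n_notify`; in sampled mode
#'   also the logical membership vectors `aware`, `downloaded`,
#'   `notifications_on`.
#' @export
engagement_cascade <- function(n, triple, mode = c("expected", "sampled"),
                               has_smartphone = NULL, u = NULL) {
  if (n <= 0) stop_config("n", "must be positive")
  mode <- match.arg(mode)
  if (mode == "expected") {
    n_aware <- round_half_up(triple$p_aware * n)
    n_download <- round_half_up(triple$p_download * n_aware)
    n_notify <- round_half_up(triple$p_notify * n_download)
    return(list(n_aware = n_aware, n_download = n_download,
                n_notify = n_notify))
  }
  if (is.null(has_smartphone)) {
    stop("sampled mode needs `has_smartphone`", call. = FALSE)
  }
  if (is.null(u)) u <- matrix(runif(3L * n), n, 3L)
  aware <- u[, 1L] < triple$p_aware
  downloaded <- aware & has_smartphone & u[, 2L] < triple$p_download
  notifications_on <- downloaded & u[, 3L] < triple$p_notify
  list(n_aware = sum(aware), n_download = sum(downloaded),
       n_notify = sum(notifications_on),
       aware = aware, downloaded = downloaded,
       notifications_on = notifications_on)
}

#' Sample per-agent app adoption states and churn times
#'
#' Runs the sampled adoption cascade and pre-draws each downloader's churn
#' day: with probability `1 - r_inf` the user discontinues at a time uniform
#' on `[0, window_days]` after introduction; otherwise she never churns
#' (`churn_day = NA`). All uniforms can be supplied (`u`, an `n x 5`
#' matrix: aware, download, notify, retain, churn time) so that adoption
#' sets are nested across engagement triples under common random numbers.
#'
#' @param agents agent `data.table` (uses `has_smartphone`).
#' @param triple an [engagement_triple()], or `NULL` for a no-app scenario
#'   (all flags false).
#' @param attrition an [attrition_params()].
#' @param u optional `n x 5` uniform matrix.
#' @return a `data.table` with logical `aware`, `downloaded`,
#'   `notifications_on` and numeric `churn_day` (days since introduction;
#'   `NA` = retained).
#' @export
sample_app_states <- function(agents, triple, attrition = attrition_params(),
                              u = NULL) {
  n <- nrow(agents)
  if (is.null(u)) u <- matrix(runif(5L * n), n, 5L)
  stopifnot(nrow(u) == n, ncol(u) == 5L)
  if (is.null(triple)) {
    return(data.table(aware = rep(FALSE, n), downloaded = rep(FALSE, n),
                      notifications_on = rep(FALSE, n),
                      churn_day = rep(NA_real_, n)))
  }
  casc <- engagement_cascade(n, triple, mode = "sampled",
                             has_smartphone = agents$has_smartphone,
                             u = u[, 1:3, drop = FALSE])
  churns <- casc$downloaded & u[, 4L] >= attrition$r_inf
  churn_day <- rep(NA_real_, n)
  churn_day[churns] <- u[churns, 5L] * attrition$window_days
  data.table(aware = casc$aware, downloaded = casc$downloaded,
             notifications_on = casc$notifications_on,
             churn_day = churn_day)
}

#' Update active-user flags for a given day
#'
#' A user is active iff she downloaded the app and either never churns or
#' her pre-drawn churn day has not yet arrived. The active fraction is
#' non-increasing in `day_since_intro` and constant after the attrition
#' window.
#'
#' @param states app-state `data.table` from [sample_app_states()].
#' @param day_since_intro days since app introduction (>= 0).
#' @return `states` with an updated logical `active` column.
#' @export
apply_attrition <- function(states, day_since_intro) {
  if (day_since_intro < 0) {
    stop("`day_since_intro` must be non-negative", call. = FALSE)
  }
  states$active <- states$downloaded &
    (is.na(states$churn_day) | day_since_intro < states$churn_day)
  states
}

#' Evening class-selection prompt
#'
#' Each evening the app asks active users with notifications on which class
#' they would like to attend the next day; a prompt is sent iff some
#' reachable center holds a class tomorrow. Prompted agents use the
#' app-modified probabilities in the perceived-access, class-awareness and
#' preparedness gates the following day.
#'
#' @param active logical n: app active this evening.
#' @param notifications_on logical n.
#' @param class_tomorrow logical n: a reachable center holds a class
#'   tomorrow.
#' @return logical vector: prompted for tomorrow.
#' @export
evening_prompt <- function(active, notifications_on, class_tomorrow) {
  active & notifications_on & class_tomorrow
}

#' Geofence notification at the home location
#'
#' True iff at least one center lies within the geofence radius of the
#' agent's home. A notified agent's perceived-access gate uses its
#' app-modified probability for that day. Evaluated once daily at the home
#' location (no within-day movement model).
#'
#' @param agents agent `data.table`.
#' @param centers center `data.table`.
#' @param radius_miles geofence radius, miles.
#' @return logical vector, one entry per agent.
#' @export
geofence_notify <- function(agents, centers, radius_miles = 0.5) {
  if (radius_miles <= 0) stop("`radius_miles` must be positive", call. = FALSE)
  if (nrow(centers) == 0L) return(rep(FALSE, nrow(agents)))
  d <- center_distances(agents, centers)
  rowSums(d <= radius_miles * MILES_TO_KM) > 0
}
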