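#' Behavioural gate probabilities
#'
#' The daily participation decision is a conjunction of five gates; gates
#' 3-5 (perceived accessibility of locations, awareness of classes,
#' preparedness with apparel/equipment) are Bernoulli with these
#' probabilities. The app-modified values are used on days the agent was
#' prompted by the app (or, for perceived access, geofence-notified) and
#' must be at least their unmodified counterparts: the app can only raise a
#' gate.
#'
#' Defaults place the unmodified gates at 0.55 each, which together with the
#' default environment puts the no-app daily participation rate near 2% at a
#' 25% baseline exercise probability.
#'
#' @param p_perceived_access probability the agent perceives a reachable
#'   center as accessible.
#' @param p_class_awareness probability she knows a class is on today.
#' @param p_prepared probability she has apparel/equipment ready.
#' @param p_perceived_access_app,p_class_awareness_app,p_prepared_app
#'   app-modified counterparts (each >= the unmodified value).
#' @return an object of class `gate_params`.
#' @export
gate_params <- function(p_perceived_access = 0.55,
                        p_class_awareness = 0.55,
                        p_prepared = 0.55,
                        p_perceived_access_app = 0.85,
                        p_class_awareness_app = 0.85,
                        p_prepared_app = 0.85) {
  g <- list(p_perceived_access = p_perceived_access,
            p_class_awareness = p_class_awareness,
            p_prepared = p_prepared,
            p_perceived_access_app = p_perceived_access_app,
            p_class_awareness_app = p_class_awareness_app,
            p_prepared_app = p_prepared_app)
  if (any(unlist(g) < 0 | unlist(g) > 1)) {
    stop_config("gate_params", "probabilities must lie in [0,1]")
  }
  for (f in c("p_perceived_access", "p_class_awareness", "p_prepared")) {
    if (g[[paste0(f, "_app")]] < g[[f]]) {
      stop_config(paste0(f, "_app"),
                  "must be at least its unmodified counterpart")
    }
  }
  structure(g, class = "gate_params")
}

#' One day's participation decision (vectorised over agents)
#'
#' An agent participates iff all five gates pass, in order: (1) a Bernoulli
#' draw at her baseline probability of wanting to exercise; (2) objective
#' access with a class available today at a reachable center
#' (`access_today`, deterministic); (3) perceived accessibility; (4) class
#' awareness; (5) preparedness. Agents prompted by the app the previous
#' evening use the app-modified probabilities in gates 3-5;
#' geofence-notified agents use the app-modified perceived-access
#' probability in gate 3.
#'
#' Gate uniforms can be supplied in `u` (an `n x 4` matrix for gates
#' 1, 3, 4, 5) to run scenarios under common random numbers; raising any
#' gate probability then never switches an agent from participating to not.
#'
#' @param baseline_prob scalar or length-n baseline exercise probability.
#' @param access_today logical n: gate 2 (reachable center holding a class
#'   today).
#' @param gates a [gate_params()] object.
#' @param prompted logical n: app evening prompt received for today.
#' @param geofence_notified logical n: geofence notification today.
#' @param u optional `n x 4` matrix of uniforms; drawn internally if `NULL`.
#' @return logical vector of participation indicators.
#' @export
daily_decision <- function(baseline_prob, access_today, gates = gate_params(),
                           prompted = FALSE, geofence_notified = FALSE,
                           u = NULL) {
  n <- length(access_today)
  if (is.null(u)) u <- matrix(runif(4L * n), n, 4L)
  stopifnot(nrow(u) == n, ncol(u) == 4L)
  p3 <- ifelse(prompted | geofence_notified,
               gates$p_perceived_access_app, gates$p_perceived_access)
  p4 <- ifelse(prompted, gates$p_class_awareness_app, gates$p_class_awareness)
  p5 <- ifelse(prompted, gates$p_prepared_app, gates$p_prepared)
  (u[, 1L] < baseline_prob) & access_today &
    (u[, 2L] < p3) & (u[, 3L] < p4) & (u[, 4L] < p5)
}

#' Average weekly physical-activity minutes
#'
#' Total class minutes divided by the number of simulated weeks.
#'
#' @param total_minutes total class minutes over the horizon (scalar or per
#'   agent).
#' @param n_days number of simulated days (must cover at least one week).
#' @return minutes per week.
#' @export
weekly_pa_minutes <- function(total_minutes, n_days) {
  if (n_days < 7) stop("need at least 7 simulated days", call. = FALSE)
  total_minutes / (n_days / 7)
}
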