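#' Built-environment specification
#'
#' Recreation-center placement and objective-accessibility parameters. Reach
#' is a binary threshold: a center is reachable on foot within
#' `walk_reach_km` of home, or by car within `drive_reach_km` when the agent
#' has one. All distance comparisons use a closed boundary (`<=`).
#'
#' @param centers_per_ward length-8 vector of center counts per ward.
#' @param geofence_radius_miles app geofence radius around the home, miles
#'   (converted at 1 mile = 1.609344 km).
#' @param walk_reach_km walking reach from home, km.
#' @param drive_reach_km driving reach from home, km (requires a car; must be
#'   at least `walk_reach_km`).
#' @param class_weekdays integer weekdays (1 = Monday ... 7 = Sunday) on
#'   which every center holds a class, by default the five weekdays.
#' @param class_duration_min class duration, minutes.
#' @param class_mets class intensity, metabolic equivalents.
#' @return an object of class `environment_spec`.
#' @export
environment_spec <- function(centers_per_ward = c(3, 3, 3, 4, 3, 6, 1, 2),
                             geofence_radius_miles = 0.5,
                             walk_reach_km = 1.0, drive_reach_km = 8.0,
                             class_weekdays = 1:5,
                             class_duration_min = 50, class_mets = 6.5) {
  spec <- list(centers_per_ward = as.integer(centers_per_ward),
               geofence_radius_miles = geofence_radius_miles,
               walk_reach_km = walk_reach_km,
               drive_reach_km = drive_reach_km,
               class_weekdays = sort(unique(as.integer(class_weekdays))),
               class_duration_min = class_duration_min,
               class_mets = class_mets)
  if (length(spec$centers_per_ward) != 8L || any(spec$centers_per_ward < 0)) {
    stop_config("centers_per_ward", "must be 8 non-negative counts")
  }
  if (spec$geofence_radius_miles <= 0) {
    stop_config("geofence_radius_miles", "must be positive")
  }
  if (spec$walk_reach_km <= 0 || spec$drive_reach_km <= 0) {
    stop_config("walk_reach_km/drive_reach_km", "must be positive")
  }
  if (spec$drive_reach_km < spec$walk_reach_km) {
    stop_config("drive_reach_km", "must be at least walk_reach_km")
  }
  if (length(spec$class_weekdays) < 1L ||
      any(!spec$class_weekdays %in% 1:7)) {
    stop_config("class_weekdays", "must be a non-empty subset of 1..7")
  }
  if (spec$class_duration_min <= 0) {
    stop_config("class_duration_min", "must be positive")
  }
  if (spec$class_mets < 1) stop_config("class_mets", "must be at least 1")
  structure(spec, class = "environment_spec")
}

#' Build the recreation-center environment
#'
#' Places `centers_per_ward[w]` centers uniformly at random inside ward
#' `w`'s rectangle and attaches the shared class schedule, duration and
#' intensity. Reproducible under `seed`.
#'
#' @param spec an [environment_spec()].
#' @param seed integer RNG seed.
#' @return a `data.table` with columns `id`, `ward_id`, `x_km`, `y_km`,
#'   `schedule` (7-character mask, Monday first, "1" = class day),
#'   `class_duration`, `class_mets`.
#' @export
build_environment <- function(spec, seed = 1L) {
  set.seed(seed)
  wb <- ward_bounds()
  ward_id <- rep(1:8, times = spec$centers_per_ward)
  m <- length(ward_id)
  mask <- paste(ifelse(1:7 %in% spec$class_weekdays, "1", "0"),
                collapse = "")
  data.table(id = seq_len(m), ward_id = ward_id,
             x_km = wb$xmin[ward_id] + runif(m) * 5,
             y_km = wb$ymin[ward_id] + runif(m) * 5,
             schedule = rep(mask, m),
             class_duration = rep(spec$class_duration_min, m),
             class_mets = rep(spec$class_mets, m))
}

# m x 7 logical matrix from the schedule masks (Monday first)
schedule_matrix <- function(centers) {
  chars <- matrix(unlist(strsplit(centers$schedule, "")),
                  nrow = nrow(centers), byrow = TRUE)
  chars == "1"
}

#' Is a class held at a center on a given simulation day?
#'
#' Day 0 of a simulation is a Monday; the weekday is `day %% 7 + 1`.
#'
#' @param centers center table (or subset) from [build_environment()].
#' @param day 0-based simulation day (scalar).
#' @return logical vector, one entry per center.
#' @export
class_available <- function(centers, day) {
  dow <- as.integer(day) %% 7L + 1L
  substr(centers$schedule, dow, dow) == "1"
}

# n_agents x n_centers Euclidean distance matrix, km
center_distances <- function(agents, centers) {
  dx <- outer(agents$home_x, centers$x_km, "-")
  dy <- outer(agents$home_y, centers$y_km, "-")
  sqrt(dx^2 + dy^2)
}

#' Objective accessibility of recreation centers
#'
#' An agent has objective access iff at least one center lies within
#' `walk_reach_km` of her home, or she has a car and one lies within
#' `drive_reach_km`. The value is fixed per agent for a given environment.
#' The population fraction with objective access is a hard ceiling on the
#' fraction that can ever participate.
#'
#' @param agents agent `data.table`.
#' @param centers center `data.table`.
#' @param spec an [environment_spec()].
#' @return logical vector, one entry per agent.
#' @export
objective_access <- function(agents, centers, spec) {
  compute_access(agents, centers, spec)$access
}

#' Centers inside the app geofence around a point
#'
#' Returns the centers whose Euclidean distance from `(x, y)` is at most
#' `radius_miles` (closed boundary), converted at 1 mile = 1.609344 km.
#'
#' @param x,y point coordinates, km.
#' @param centers center `data.table`.
#' @param radius_miles geofence radius, miles.
#' @return the subset of `centers` inside the geofence (possibly empty).
#' @export
centers_within_geofence <- function(x, y, centers, radius_miles = 0.5) {
  if (radius_miles <= 0) stop("`radius_miles` must be positive", call. = FALSE)
  d <- sqrt((centers$x_km - x)^2 + (centers$y_km - y)^2)
  centers[d <= radius_miles * MILES_TO_KM]
}

#' Precompute per-agent accessibility structures
#'
#' One pass over the agent-center distance matrix yields everything the day
#' loop needs: the objective-access flag, for each weekday whether any
#' reachable center holds a class (`by_dow`), the nearest reachable center
#' holding a class on each weekday (`chosen`, 0 when none -- this center's
#' duration and intensity define the session the agent would attend), and
#' whether any center sits inside the home geofence (`geofenced`).
#'
#' @param agents agent `data.table`.
#' @param centers center `data.table`.
#' @param spec an [environment_spec()].
#' @return list with `access` (logical n), `by_dow` (n x 7 logical),
#'   `chosen` (n x 7 integer row index into `centers`), `geofenced`
#'   (logical n).
#' @export
compute_access <- function(agents, centers, spec) {
  n <- nrow(agents)
  m <- nrow(centers)
  if (m == 0L) {
    return(list(access = rep(FALSE, n),
                by_dow = matrix(FALSE, n, 7),
                chosen = matrix(0L, n, 7),
                geofenced = rep(FALSE, n)))
  }
  d <- center_distances(agents, centers)
  reach <- d <= spec$walk_reach_km |
    (agents$has_car & d <= spec$drive_reach_km)
  sched <- schedule_matrix(centers)
  by_dow <- matrix(FALSE, n, 7)
  chosen <- matrix(0L, n, 7)
  for (dow in 1:7) {
    open <- which(sched[, dow])
    if (length(open) == 0L) next
    dd <- d[, open, drop = FALSE]
    dd[!reach[, open, drop = FALSE]] <- Inf
    nearest <- max.col(-dd, ties.method = "first")
    ok <- dd[cbind(seq_len(n), nearest)] < Inf
    by_dow[, dow] <- ok
    chosen[ok, dow] <- open[nearest[ok]]
  }
  list(access = rowSums(reach) > 0,
       by_dow = by_dow,
       chosen = chosen,
       geofenced = rowSums(d <= spec$geofence_radius_miles * MILES_TO_KM) > 0)
}

#' Write / read the center table as CSV
#'
#' @param centers center `data.table`.
#' @param path CSV file path.
#' @return `read_centers()` returns the center `data.table`.
#' @export
write_centers <- function(centers, path) {
  fwrite(centers, path)
  invisible(path)
}

#' @rdname write_centers
#' @export
read_centers <- function(path) {
  x <- fread(path, colClasses = list(character = "schedule"))
  setDT(x)
  x
}
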