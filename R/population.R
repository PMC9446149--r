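#' Synthetic population specification
#'
#' Parameters of the synthetic agent population: adult women aged 18-65
#' distributed over eight wards. Defaults emulate a study population of
#' 167,356 women with roughly 80% smartphone ownership; all distributions
#' are parametric stand-ins for the census microdata a city-specific build
#' would use.
#'
#' @param n_agents number of agents.
#' @param ward_shares length-8 vector of ward population shares (sums to 1).
#' @param smartphone_ownership probability an agent owns a smartphone.
#' @param car_ownership length-8 vector: per-ward probability of car access.
#' @param age_range min/max age in years; ages are uniform on the range.
#' @param height_mean,height_sd height distribution, metres (normal, clamped
#'   to 1.40-2.00 m).
#' @param bmi_meanlog,bmi_sdlog initial BMI distribution, lognormal
#'   parameters (clamped to 16-60 kg/m^2). The initial prevalence of
#'   overweight/obesity is set entirely by this choice.
#' @param income_meanlog,income_sdlog annual income, lognormal parameters.
#'   Income is carried as an attribute but has no behavioural mechanism by
#'   default.
#' @param seed integer RNG seed for [generate_population()].
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_agents = 167356L,
                            ward_shares = rep(1 / 8, 8),
                            smartphone_ownership = 0.80,
                            car_ownership = rep(0.55, 8),
                            age_range = c(18, 65),
                            height_mean = 1.63, height_sd = 0.07,
                            bmi_meanlog = log(30.5), bmi_sdlog = 0.18,
                            income_meanlog = log(45000), income_sdlog = 0.5,
                            seed = 1L) {
  spec <- list(n_agents = as.integer(n_agents), ward_shares = ward_shares,
               smartphone_ownership = smartphone_ownership,
               car_ownership = car_ownership, age_range = age_range,
               height_mean = height_mean, height_sd = height_sd,
               bmi_meanlog = bmi_meanlog, bmi_sdlog = bmi_sdlog,
               income_meanlog = income_meanlog, income_sdlog = income_sdlog,
               seed = as.integer(seed))
  validate_population_spec(spec)
  structure(spec, class = "population_spec")
}

validate_population_spec <- function(spec) {
  if (!length(spec$n_agents) == 1L || is.na(spec$n_agents) ||
      spec$n_agents <= 0L) {
    stop_config("n_agents", "must be a single positive integer")
  }
  if (length(spec$ward_shares) != 8L || any(spec$ward_shares < 0)) {
    stop_config("ward_shares", "must be 8 non-negative proportions")
  }
  if (abs(sum(spec$ward_shares) - 1) > 1e-9) {
    stop_config("ward_shares", "must sum to 1 (within 1e-9)")
  }
  if (spec$smartphone_ownership < 0 || spec$smartphone_ownership > 1) {
    stop_config("smartphone_ownership", "must be a probability in [0,1]")
  }
  if (length(spec$car_ownership) != 8L || any(spec$car_ownership < 0) ||
      any(spec$car_ownership > 1)) {
    stop_config("car_ownership", "must be 8 probabilities in [0,1]")
  }
  if (length(spec$age_range) != 2L || spec$age_range[1] < 18 ||
      spec$age_range[2] > 65 || diff(spec$age_range) < 0) {
    stop_config("age_range", "must lie within [18, 65]")
  }
  if (spec$height_mean <= 0 || spec$height_sd < 0) {
    stop_config("height_mean/height_sd", "must be positive")
  }
  if (spec$bmi_sdlog < 0) stop_config("bmi_sdlog", "must be non-negative")
  invisible(spec)
}

#' Ward geometry
#'
#' The city is an abstract mosaic of eight 5 km x 5 km ward rectangles
#' arranged in a 2 x 4 grid (20 km x 10 km overall). Only relative distances
#' matter to the behavioural mechanism, so no real geography is used.
#'
#' @return a `data.table` with columns `ward_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax` (km).
#' @export
ward_bounds <- function() {
  ward_id <- 1:8
  col <- (ward_id - 1L) %% 4L
  row <- (ward_id - 1L) %/% 4L
  data.table(ward_id = ward_id,
             xmin = col * 5, xmax = col * 5 + 5,
             ymin = row * 5, ymax = row * 5 + 5)
}

#' Generate a synthetic agent population
#'
#' Draws `n_agents` agents: ward assignment multinomial in `ward_shares`,
#' home location uniform within the agent's ward rectangle, work location
#' uniform over the whole city, smartphone/car flags Bernoulli at the
#' configured rates, and body composition initialised from BMI, age and
#' height via [init_body_composition()]. Fully reproducible for a fixed
#' `spec$seed`.
#'
#' @param spec a [population_spec()].
#' @param baseline_exercise_prob per-day probability of wanting to exercise;
#'   a scenario-level quantity, stored on each agent (may be `NA` until a
#'   scenario assigns it).
#' @return a `data.table` with one row per agent and columns `id`, `age`,
#'   `height`, `fat_mass`, `lean_mass`, `ward_id`, `home_x`, `home_y`,
#'   `work_x`, `work_y`, `income`, `has_car`, `has_smartphone`,
#'   `baseline_exercise_prob`.
#' @export
generate_population <- function(spec, baseline_exercise_prob = NA_real_) {
  validate_population_spec(spec)
  if (!is.na(baseline_exercise_prob) &&
      (baseline_exercise_prob < 0 || baseline_exercise_prob > 1)) {
    stop_config("baseline_exercise_prob", "must be a probability in [0,1]")
  }
  n <- spec$n_agents
  set.seed(spec$seed)
  wb <- ward_bounds()

  ward_id <- sample.int(8L, n, replace = TRUE, prob = spec$ward_shares)
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  height <- pmin(pmax(rnorm(n, spec$height_mean, spec$height_sd), 1.40), 2.00)
  bmi <- pmin(pmax(rlnorm(n, spec$bmi_meanlog, spec$bmi_sdlog), 16), 60)
  comp <- init_body_composition(bmi, age, height)
  home_x <- wb$xmin[ward_id] + runif(n) * 5
  home_y <- wb$ymin[ward_id] + runif(n) * 5
  work_x <- runif(n, 0, 20)
  work_y <- runif(n, 0, 10)
  income <- rlnorm(n, spec$income_meanlog, spec$income_sdlog)
  has_car <- runif(n) < spec$car_ownership[ward_id]
  has_smartphone <- runif(n) < spec$smartphone_ownership

  data.table(id = seq_len(n), age = age, height = height,
             fat_mass = comp$fat_mass, lean_mass = comp$lean_mass,
             ward_id = ward_id, home_x = home_x, home_y = home_y,
             work_x = work_x, work_y = work_y, income = income,
             has_car = has_car, has_smartphone = has_smartphone,
             baseline_exercise_prob = baseline_exercise_prob)
}

#' Split BMI-implied weight into fat and lean mass
#'
#' Weight is `bmi * height^2`; the fat fraction comes from the Deurenberg
#' body-fat equation for women, `BF% = 1.2*BMI + 0.23*age - 5.4`, clamped to
#' the fraction range `[0.05, 0.60]`. Mass is conserved exactly:
#' `fat + lean = bmi * height^2`.
#'
#' @param bmi body-mass index, kg/m^2 (must exceed 10; vectorised).
#' @param age age in years.
#' @param height height in metres.
#' @param bf_clamp admissible body-fat fraction range.
#' @return list with `fat_mass` and `lean_mass`, kg.
#' @export
init_body_composition <- function(bmi, age, height,
                                  bf_clamp = c(0.05, 0.60)) {
  if (any(height <= 0)) stop("`height` must be positive", call. = FALSE)
  if (any(bmi <= 10)) stop("`bmi` must exceed 10", call. = FALSE)
  weight <- bmi * height^2
  bf <- (1.2 * bmi + 0.23 * age - 5.4) / 100
  bf <- pmin(pmax(bf, bf_clamp[1]), bf_clamp[2])
  fat <- bf * weight
  list(fat_mass = fat, lean_mass = weight - fat)
}

#' Write / read an agent population as CSV
#'
#' One row per agent, columns exactly the agent fields produced by
#' [generate_population()].
#'
#' @param agents agent `data.table`.
#' @param path CSV file path.
#' @return `read_population()` returns the agent `data.table`.
#' @export
write_population <- function(agents, path) {
  fwrite(agents, path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  agents <- fread(path)
  setDT(agents)
  agents
}
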