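#' Metabolic model parameters
#'
#' Constants of the two-compartment (fat mass / lean mass) energy-balance
#' model that converts each agent's daily caloric surplus or deficit into
#' mass changes.
#'
#' Energy imbalances are split between the compartments by a Forbes
#' partition, `p = forbes_c / (forbes_c + fat_mass)`, the lean share of the
#' change; each compartment then changes by its share divided by its energy
#' density. Maintenance expenditure is a physical-activity-level multiple of
#' a resting metabolic rate linear in lean (fat-free) mass, in the
#' Cunningham style: `TEE = pal * (rmr_slope * lean + rmr_intercept)`.
#'
#' @param rho_fat energy density of fat tissue, kcal/kg.
#' @param rho_lean energy density of lean tissue, kcal/kg.
#' @param forbes_c Forbes constant, kg; controls how the lean share of a mass
#'   change falls as fat mass rises.
#' @param rmr_slope resting metabolic rate per kg of lean mass, kcal/day/kg.
#' @param rmr_intercept resting metabolic rate intercept, kcal/day.
#' @param pal physical-activity level multiplier on RMR (dimensionless),
#'   covering all non-class activity.
#' @param met_resting_subtracted if `TRUE` (default) class energy uses net
#'   METs (`mets - 1`), since resting expenditure during the class is already
#'   counted inside TEE; `FALSE` uses gross METs.
#' @param lean_floor,fat_floor lower bounds, kg, below which a compartment is
#'   not allowed to fall (any residual deficit is discarded).
#' @return an object of class `metabolic_params`.
#' @export
metabolic_params <- function(rho_fat = 9440, rho_lean = 1807,
                             forbes_c = 10.4, rmr_slope = 19.7,
                             rmr_intercept = 413, pal = 1.5,
                             met_resting_subtracted = TRUE,
                             lean_floor = 25, fat_floor = 2) {
  p <- list(rho_fat = rho_fat, rho_lean = rho_lean, forbes_c = forbes_c,
            rmr_slope = rmr_slope, rmr_intercept = rmr_intercept, pal = pal,
            met_resting_subtracted = isTRUE(met_resting_subtracted),
            lean_floor = lean_floor, fat_floor = fat_floor)
  for (f in c("rho_fat", "rho_lean", "forbes_c", "pal")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop_config(f, "must be a single strictly positive number")
    }
  }
  structure(p, class = "metabolic_params")
}

#' Energy expended in an exercise class
#'
#' One MET is 1 kcal per kg of body weight per hour, so
#' `kcal = (mets - 1) * weight * minutes / 60` in the default net mode
#' (resting expenditure subtracted), or with `mets` unreduced in gross mode.
#' Class energy scales with the agent's current body weight, so heavier
#' agents burn more per class.
#'
#' @param weight body weight, kg (vectorised).
#' @param mets class intensity in metabolic equivalents.
#' @param minutes class duration, minutes.
#' @param params a [metabolic_params()] object.
#' @return kcal expended (vector).
#' @export
exercise_kcal <- function(weight, mets, minutes, params = metabolic_params()) {
  if (any(minutes < 0)) stop("`minutes` must be non-negative", call. = FALSE)
  stopifnot(all(weight > 0))
  eff <- if (params$met_resting_subtracted) mets - 1 else mets
  eff * weight * minutes / 60
}

#' Total daily maintenance expenditure
#'
#' Expenditure outside the modeled classes: a physical-activity-level
#' multiple of a resting metabolic rate linear in lean mass. Strictly
#' increasing in lean mass whenever `rmr_slope > 0`.
#'
#' @param lean_mass lean (fat-free) mass, kg (vectorised).
#' @param params a [metabolic_params()] object.
#' @return kcal/day (vector).
#' @export
total_expenditure <- function(lean_mass, params = metabolic_params()) {
  stopifnot(all(lean_mass > 0))
  params$pal * (params$rmr_slope * lean_mass + params$rmr_intercept)
}

#' Apply one day's energy balance to body composition
#'
#' The net balance `net_kcal = intake - TEE - exercise` is split between the
#' lean and fat compartments with the Forbes partition
#' `p = forbes_c / (forbes_c + fat_mass)` (lean share), each divided by its
#' tissue energy density. Compartments are floored at `lean_floor` /
#' `fat_floor`; a deficit that would push a compartment below its floor is
#' discarded rather than redirected.
#'
#' @param fat_mass,lean_mass current compartment masses, kg (vectorised).
#' @param net_kcal net energy balance for the day, kcal.
#' @param params a [metabolic_params()] object.
#' @return list with updated `fat_mass` and `lean_mass`.
#' @export
update_composition <- function(fat_mass, lean_mass, net_kcal,
                               params = metabolic_params()) {
  stopifnot(all(fat_mass >= 0), all(lean_mass > 0))
  p <- params$forbes_c / (params$forbes_c + fat_mass)
  list(
    fat_mass  = pmax(fat_mass + (1 - p) * net_kcal / params$rho_fat,
                     params$fat_floor),
    lean_mass = pmax(lean_mass + p * net_kcal / params$rho_lean,
                     params$lean_floor)
  )
}

#' BMI and weight category
#'
#' `bmi = (fat + lean) / height^2`. Categories are disjoint: `"overweight"`
#' is `25 <= BMI < 30`, `"obese"` is `BMI >= 30` (closed lower boundaries),
#' `"normal"` is anything below 25.
#'
#' @param fat_mass,lean_mass compartment masses, kg (vectorised).
#' @param height height, m.
#' @return list with numeric `bmi` and character `category`.
#' @export
bmi_and_category <- function(fat_mass, lean_mass, height) {
  if (any(height <= 0)) stop("`height` must be positive", call. = FALSE)
  bmi <- (fat_mass + lean_mass) / height^2
  category <- ifelse(bmi >= 30, "obese",
                     ifelse(bmi >= 25, "overweight", "normal"))
  list(bmi = bmi, category = category)
}

#' Calibrate daily caloric intake to hold initial weight
#'
#' Intake is fixed at the value that makes the daily energy balance exactly
#' zero at the agent's initial body composition with zero class
#' participation, i.e. `intake = TEE(initial lean mass)`. Weight is then
#' stationary absent the intervention, and compensatory eating is excluded
#' by construction: intake never changes during a simulation.
#'
#' @param lean_mass initial lean mass, kg (vectorised).
#' @param params a [metabolic_params()] object.
#' @return kcal/day intake (vector).
#' @export
calibrate_intake <- function(lean_mass, params = metabolic_params()) {
  total_expenditure(lean_mass, params)
}
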