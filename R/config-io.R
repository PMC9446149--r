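#' Read / write a scenario configuration as YAML
#'
#' The declarative file mirrors the constructor arguments, grouped by
#' section: `population`, `environment`, `gates`, `metabolic`, `engagement`
#' (keys `p_aware`, `p_download`, `p_notify`, `mode`; omit the section for a
#' no-app scenario), `attrition` (`r_inf`, `window_days`), `app`
#' (`intro_day`) and top-level `baseline_exercise_prob`, `horizon_years`,
#' `replicates`, `seed`. Unknown keys raise an error naming the key; missing
#' keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return `read_scenario_config()` returns a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("population", "environment", "gates", "metabolic",
             "engagement", "attrition", "app", "baseline_exercise_prob",
             "horizon_years", "replicates", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_config(bad[1], "is not a recognised configuration key")
  }
  call_with <- function(fun, args, section) {
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad)) {
      stop_config(paste(section, bad[1], sep = "."),
                  "is not a recognised configuration key")
    }
    do.call(fun, args)
  }
  engagement <- NULL
  mode <- "sampled"
  if (!is.null(raw$engagement)) {
    e <- raw$engagement
    if (!is.null(e$mode)) {
      mode <- e$mode
      e$mode <- NULL
    }
    engagement <- call_with(engagement_triple, e, "engagement")
  }
  scenario_config(
    population = call_with(population_spec,
                           raw$population %||% list(), "population"),
    environment = call_with(environment_spec,
                            raw$environment %||% list(), "environment"),
    gates = call_with(gate_params, raw$gates %||% list(), "gates"),
    metabolic = call_with(metabolic_params,
                          raw$metabolic %||% list(), "metabolic"),
    engagement = engagement,
    attrition = call_with(attrition_params,
                          raw$attrition %||% list(), "attrition"),
    baseline_exercise_prob = raw$baseline_exercise_prob %||% 0.25,
    horizon_years = raw$horizon_years %||% 5,
    replicates = raw$replicates %||% 10L,
    seed = raw$seed %||% 1L,
    app_intro_day = (raw$app %||% list())$intro_day %||% 0L,
    engagement_mode = mode
  )
}

#' @param config a [scenario_config()] to serialise.
#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(
    population = unclass(config$population),
    environment = unclass(config$environment),
    gates = unclass(config$gates),
    metabolic = unclass(config$metabolic),
    attrition = unclass(config$attrition),
    app = list(intro_day = config$app_intro_day),
    baseline_exercise_prob = config$baseline_exercise_prob,
    horizon_years = config$horizon_years,
    replicates = config$replicates,
    seed = config$seed
  )
  if (!is.null(config$engagement)) {
    out$engagement <- c(unclass(config$engagement),
                        list(mode = config$engagement_mode))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
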