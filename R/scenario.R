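## Scenario specifications: the four generative models of individual decline.

.scenario_levels <- c(
  S1 = "S1_uniform_relative",
  S2 = "S2_uniform_absolute",
  S3 = "S3_random_individual",
  S4 = "S4_convergent"
)

.spec_fields <- c(
  "scenario_id", "baseline_age", "max_age", "baseline_mean", "baseline_sd",
  "relative_rate", "absolute_rate", "slope_mean", "slope_sd",
  "convergence_floor", "convergence_rate", "noise_sd"
)

#' Specify a generative model of age-related decline
#'
#' A scenario specification fully parameterises one of four population models
#' of how a physiological function (muscle power, VO2max, a cognitive score,
#' ...) declines between a baseline age and a maximum age. Every individual
#' starts from a baseline value drawn from a normal distribution (truncated
#' below so values stay admissible) and then declines linearly in age:
#'
#' * `S1_uniform_relative` ("uniform" ageing): everyone loses the same
#'   *fraction* `relative_rate` of their own baseline per year, so ranking and
#'   relative spread are preserved. SD shrinks with age; COVAR stays constant.
#' * `S2_uniform_absolute`: everyone loses the same *absolute* amount
#'   `absolute_rate` per year. SD stays constant; COVAR grows.
#' * `S3_random_individual`: each individual draws a personal annual decrement
#'   from a normal distribution (`slope_mean`, `slope_sd`) truncated at zero,
#'   independent of the baseline. Both SD and COVAR grow.
#' * `S4_convergent`: the higher an individual starts above a common floor
#'   `convergence_floor`, the more they lose — the annual loss is
#'   `convergence_rate * (baseline - convergence_floor)`, so trajectories
#'   converge. Both SD and COVAR shrink.
#'
#' Measurement error is additive Gaussian noise with standard deviation
#' `noise_sd` (in function units), applied per observation at simulation time;
#' the closed-form moments in [analytic_moments()] describe the noise-free
#' population.
#'
#' Defaults give a population with baseline mean 100 and SD 9 function units
#' observed between ages 30 and 80. The baseline SD is chosen as the largest
#' value for which the default absolute loss (1 unit/year) keeps every
#' trajectory safely positive at the maximum age (a > 5.5 sigma margin), so
#' large simulated cohorts do not produce inadmissible negative values.
#'
#' @param scenario Scenario identifier: `"S1"`..`"S4"` or the full labels
#'   `"S1_uniform_relative"`, `"S2_uniform_absolute"`, `"S3_random_individual"`,
#'   `"S4_convergent"`.
#' @param baseline_age Age (years) at which baselines are defined. Default 30.
#' @param max_age Upper end of the modelled age range (years). Default 80.
#' @param baseline_mean Mean of the baseline distribution (function units,
#'   > 0). Default 100.
#' @param baseline_sd SD of the baseline distribution (function units, >= 0).
#'   Default 9.
#' @param relative_rate S1 only: fraction of the individual baseline lost per
#'   year. Default 0.01 (1 %/year, halving the function over 50 years).
#' @param absolute_rate S2 only: function units lost per year. Default 1.
#' @param slope_mean,slope_sd S3 only: mean and SD (units/year) of the parent
#'   normal distribution of individual decline rates, truncated at 0.
#'   Defaults 0.5 and 0.2.
#' @param convergence_floor S4 only: common floor (function units, >= 0)
#'   towards which trajectories converge. Default 20.
#' @param convergence_rate S4 only: fraction of the gap above the floor lost
#'   per year. Default 0.016 (closing 80 % of the gap over 50 years).
#' @param noise_sd SD of additive measurement noise (function units, >= 0).
#'   Default 0 (noise-free, as in the idealised illustration).
#'
#' @return An object of class `scenario_spec`: a named list with the fields
#'   above (scenario id stored in its full form).
#' @examples
#' spec <- scenario_spec("S1")
#' spec
#' analytic_moments(spec, c(30, 55, 80))
#' @export
scenario_spec <- function(scenario,
                          baseline_age = 30,
                          max_age = 80,
                          baseline_mean = 100,
                          baseline_sd = 9,
                          relative_rate = 0.01,
                          absolute_rate = 1,
                          slope_mean = 0.5,
                          slope_sd = 0.2,
                          convergence_floor = 20,
                          convergence_rate = 0.016,
                          noise_sd = 0) {
  scenario_id <- match_scenario(scenario)
  num <- function(x) if (is.numeric(x)) as.numeric(x) else x
  spec <- structure(
    list(
      scenario_id = scenario_id,
      baseline_age = num(baseline_age),
      max_age = num(max_age),
      baseline_mean = num(baseline_mean),
      baseline_sd = num(baseline_sd),
      relative_rate = num(relative_rate),
      absolute_rate = num(absolute_rate),
      slope_mean = num(slope_mean),
      slope_sd = num(slope_sd),
      convergence_floor = num(convergence_floor),
      convergence_rate = num(convergence_rate),
      noise_sd = num(noise_sd)
    ),
    class = "scenario_spec"
  )
  validate_scenario_spec(spec)
}

match_scenario <- function(scenario) {
  stopifnot(is.character(scenario), length(scenario) == 1L)
  if (scenario %in% names(.scenario_levels)) {
    return(unname(.scenario_levels[scenario]))
  }
  if (scenario %in% .scenario_levels) {
    return(scenario)
  }
  abort_config(sprintf(
    "Unknown scenario '%s'; expected one of %s.",
    scenario, paste(c(names(.scenario_levels), .scenario_levels), collapse = ", ")
  ))
}

short_scenario <- function(scenario_id) {
  names(.scenario_levels)[match(scenario_id, .scenario_levels)]
}

#' @export
print.scenario_spec <- function(x, ...) {
  span <- x$max_age - x$baseline_age
  cat(sprintf(
    "<scenario_spec> %s\n  ages %g-%g, baseline ~ N(%g, %g^2), noise sd %g\n",
    x$scenario_id, x$baseline_age, x$max_age,
    x$baseline_mean, x$baseline_sd, x$noise_sd
  ))
  rate <- switch(short_scenario(x$scenario_id),
    S1 = sprintf("relative loss %g of baseline per year (%.0f%% left at age %g)",
                 x$relative_rate, 100 * (1 - x$relative_rate * span), x$max_age),
    S2 = sprintf("absolute loss %g units per year", x$absolute_rate),
    S3 = sprintf("individual slopes ~ N(%g, %g^2) truncated at 0 units/year",
                 x$slope_mean, x$slope_sd),
    S4 = sprintf("loss %g of the gap above floor %g per year",
                 x$convergence_rate, x$convergence_floor)
  )
  cat("  ", rate, "\n", sep = "")
  invisible(x)
}

#' Validate a scenario specification
#'
#' Checks the structural invariants that keep every linear trajectory
#' admissible over the modelled age range: positive baseline mean, non-negative
#' dispersion and rate parameters, `max_age > baseline_age`, a relative rate
#' that cannot drive S1 values negative within the range
#' (`relative_rate * (max_age - baseline_age) <= 1`), and a convergence rate
#' that cannot push S4 values through their floor
#' (`convergence_rate * (max_age - baseline_age) <= 1`, `convergence_floor >= 0`).
#'
#' @param spec A `scenario_spec`.
#' @return `spec`, invisibly unchanged, if valid; otherwise an error of class
#'   `agecovar_error_config`.
#' @export
validate_scenario_spec <- function(spec) {
  if (!inherits(spec, "scenario_spec")) {
    abort_contract("`spec` must be a scenario_spec object.")
  }
  num_fields <- setdiff(.spec_fields, "scenario_id")
  for (f in num_fields) {
    if (!is_number(spec[[f]])) {
      abort_config(sprintf("Field '%s' must be a single finite number.", f))
    }
  }
  if (spec$baseline_mean <= 0) abort_config("baseline_mean must be > 0.")
  for (f in c("baseline_sd", "relative_rate", "absolute_rate", "slope_mean",
              "slope_sd", "convergence_floor", "convergence_rate", "noise_sd")) {
    if (spec[[f]] < 0) abort_config(sprintf("%s must be >= 0.", f))
  }
  if (spec$max_age <= spec$baseline_age) {
    abort_config("max_age must be greater than baseline_age.")
  }
  span <- spec$max_age - spec$baseline_age
  sid <- short_scenario(spec$scenario_id)
  if (sid == "S1" && spec$relative_rate * span > 1) {
    abort_config(sprintf(
      "relative_rate * age span = %g exceeds 1: S1 values would go negative within the age range.",
      spec$relative_rate * span
    ))
  }
  if (sid == "S4" && spec$convergence_rate * span > 1) {
    abort_config(sprintf(
      "convergence_rate * age span = %g exceeds 1: S4 values would cross their floor.",
      spec$convergence_rate * span
    ))
  }
  invisible(spec)
}

#' Read and write scenario specifications as flat JSON
#'
#' A `scenario_spec` round-trips through a flat key-value JSON file whose keys
#' are exactly the field names of [scenario_spec()]. Unknown keys are rejected
#' rather than ignored, so a typo in a config file cannot silently fall back
#' to a default.
#'
#' @param spec A `scenario_spec`.
#' @param path File path.
#' @return `write_scenario_spec()` returns `path` invisibly;
#'   `read_scenario_spec()` returns a validated `scenario_spec`.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_scenario_spec(scenario_spec("S3"), path)
#' read_scenario_spec(path)
#' @export
write_scenario_spec <- function(spec, path) {
  validate_scenario_spec(spec)
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_spec
#' @export
read_scenario_spec <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("No such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec_from_list(raw)
}

## Build a scenario_spec from a plain named list, rejecting unknown keys.
spec_from_list <- function(raw) {
  if (is.null(names(raw)) || any(names(raw) == "")) {
    abort_parse("Scenario config must be a named key-value mapping.")
  }
  unknown <- setdiff(names(raw), .spec_fields)
  if (length(unknown)) {
    abort_parse(sprintf(
      "Unknown scenario config key(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  if (is.null(raw$scenario_id)) abort_parse("Scenario config lacks 'scenario_id'.")
  args <- raw[setdiff(names(raw), "scenario_id")]
  names(args) <- names(args)
  do.call(scenario_spec, c(list(scenario = raw$scenario_id), args))
}
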