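#' One-at-a-time sensitivity sweep specification
#'
#' Describes a three-point (lower/base/upper) sweep of a single model lever.
#' `parameter_name` is either a [parameter_set()] field, `"pass_rate"`
#' (which moves the first-time and re-take pass rates together by the same
#' offset, as sensitivity ranges for the exam are published in pairs),
#' `"prescriptions_per_person_multiplier"` (scales the whole age-rate
#' table), or `"population_variant"` (lower/base/upper are alternative
#' [population_projection()] inputs, e.g. low-birth/high-death and
#' high-birth/low-death demographic variants).
#'
#' @param parameter_name The swept lever (see above).
#' @param lower,base,upper The three levels (numbers, or population
#'   projections for `"population_variant"`).
#' @param report_years Years at which the `TOTAL` sufficiency ratio is
#'   reported.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter_name, lower, base, upper,
                       report_years = c(2025L, 2040L)) {
  if (parameter_name != "population_variant") {
    stopifnot(is.numeric(lower), is.numeric(base), is.numeric(upper))
    if (!(lower <= base && base <= upper)) {
      stop("need lower <= base <= upper", call. = FALSE)
    }
  }
  structure(list(parameter_name = parameter_name, lower = lower, base = base,
                 upper = upper, report_years = as.integer(report_years)),
            class = "sweep_spec")
}

#' @rdname run_scenarios
#' @param label Scenario name.
#' @param shares A [diffusion_shares()] (or object coercible by it).
#' @export
scenario_spec <- function(label, shares) {
  if (!inherits(shares, "diffusion_shares")) {
    shares <- diffusion_shares(shares, label = label)
  }
  structure(list(label = label, shares = shares), class = "scenario_spec")
}

# Run the full supply -> demand -> sufficiency pipeline for one input
# combination and return TOTAL (or per-area) ratios at the report years.
pipeline_ratios <- function(params, initial, shares, pop, rates,
                            report_years, areas_too = FALSE) {
  years <- sort(unique(pop$year))
  supply <- simulate_supply(initial, params, shares, years[1],
                            horizon = length(years) - 1L)
  demand <- demand_trajectory(pop, rates, params, years)
  rep <- build_report(supply, demand, params)
  rep <- rep[rep$year %in% report_years, ]
  if (!areas_too) rep <- rep[rep$area_id == "TOTAL", ]
  rep[, c("area_id", "year", "ratio")]
}

baseline_pieces <- function(baseline) {
  need <- c("params", "initial", "shares", "population", "rates")
  miss <- setdiff(need, names(baseline))
  if (length(miss)) {
    stop(sprintf("baseline inputs lack: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  baseline
}

#' Run a one-at-a-time sensitivity sweep
#'
#' Reruns the full supply/demand/sufficiency pipeline at each of the three
#' sweep levels, all other parameters held bit-identical to base, and
#' reports the `TOTAL` sufficiency ratio at the report years.
#'
#' @param spec A [sweep_spec()].
#' @param baseline Baseline inputs: a [gen_baseline_calibrated()] bundle or
#'   any list with elements `params`, `initial`, `shares`, `population`,
#'   `rates`.
#' @return A tibble with columns
#'   `parameter, level, value, area_id, year, ratio` (`value` is `NA` for
#'   population variants).
#' @export
run_sweep <- function(spec, baseline) {
  stopifnot(inherits(spec, "sweep_spec"))
  b <- baseline_pieces(baseline)
  levels <- list(lower = spec$lower, base = spec$base, upper = spec$upper)
  known_params <- names(formals(parameter_set))

  one <- function(level_name, level_value) {
    params <- b$params
    pop <- b$population
    rates <- b$rates
    pn <- spec$parameter_name
    if (pn == "pass_rate") {
      offset <- level_value - params$pass_rate_first
      params$pass_rate_first <- level_value
      params$pass_rate_retake <- params$pass_rate_retake + offset
      params <- validate_parameter_set(params)
    } else if (pn == "prescriptions_per_person_multiplier") {
      rates <- age_rates(stats::setNames(unclass(rates) * level_value,
                                         names(rates)))
    } else if (pn == "population_variant") {
      pop <- level_value
      stopifnot(inherits(pop, "population_projection"))
    } else if (pn %in% known_params) {
      params[[pn]] <- level_value
      params <- validate_parameter_set(params)
    } else {
      stop(sprintf("unknown sweep parameter '%s'", pn), call. = FALSE)
    }
    res <- pipeline_ratios(params, b$initial, b$shares, pop, rates,
                           spec$report_years)
    res$parameter <- pn
    res$level <- level_name
    res$value <- if (is.numeric(level_value)) level_value else NA_real_
    res
  }

  out <- dplyr::bind_rows(Map(one, names(levels), levels))
  tibble::as_tibble(out[, c("parameter", "level", "value", "area_id", "year",
                            "ratio")])
}

#' Run diffusion scenario analyses
#'
#' Reruns the pipeline once per scenario, each with its own allocation of
#' newly licensed pharmacists across areas, and reports per-area (plus
#' `TOTAL`) sufficiency ratios at the report years.
#'
#' @param specs A list of `scenario_spec()` objects.
#' @param baseline Baseline inputs as in [run_sweep()].
#' @param report_years Years at which ratios are reported.
#' @return A tibble with columns `scenario, area_id, year, ratio`.
#' @export
run_scenarios <- function(specs, baseline, report_years = c(2025L, 2040L)) {
  b <- baseline_pieces(baseline)
  one <- function(sc) {
    stopifnot(inherits(sc, "scenario_spec"))
    res <- pipeline_ratios(b$params, b$initial, sc$shares, b$population,
                           b$rates, as.integer(report_years), areas_too = TRUE)
    res$scenario <- sc$label
    res
  }
  out <- dplyr::bind_rows(lapply(specs, one))
  tibble::as_tibble(out[, c("scenario", "area_id", "year", "ratio")])
}
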