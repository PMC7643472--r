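pop_slice <- function(pop, area, year) {
  if (identical(area, "TOTAL")) {
    sub <- pop[pop$year == year, ]
  } else {
    sub <- pop[pop$area_id == area & pop$year == year, ]
  }
  if (nrow(sub) == 0) {
    stop(sprintf("population projection has no data for area '%s', year %s",
                 area, year), call. = FALSE)
  }
  tapply(sub$persons, sub$age_group, sum)
}

#' Project annual prescription volume for one area and year
#'
#' The demographic demand driver: the sum over 5-year age groups of
#' projected population times the age-specific prescriptions per person per
#' year. Rates are held constant over the horizon; demographic change alone
#' moves the projection.
#'
#' @param pop A [population_projection()].
#' @param rates An [age_rates()] vector.
#' @param area An area id, or `"TOTAL"` for the prefecture-wide sum.
#' @param year Calendar year.
#' @return Prescriptions per year (non-negative scalar).
#' @export
#' @examples
#' pop <- population_projection(data.frame(
#'   area_id = "A", year = 2015, age_group = age_groups_5yr(),
#'   persons = 1000))
#' r <- age_rates(stats::setNames(rep(2, 18), age_groups_5yr()))
#' project_prescriptions(pop, r, "A", 2015)
project_prescriptions <- function(pop, rates, area, year) {
  counts <- pop_slice(pop, area, year)
  missing <- setdiff(names(rates), names(counts))
  if (length(missing)) {
    stop(sprintf("population for area '%s', year %s lacks age group(s): %s",
                 area, year, paste(missing, collapse = ", ")), call. = FALSE)
  }
  sum(counts[names(rates)] * as.numeric(rates))
}

#' Project pharmacist demand in prescription-equivalents
#'
#' Prescription volume divided by the demand coefficient: prescriptions
#' occupy only that fraction of pharmacist work time, so total demand
#' expressed on the prescription scale is correspondingly larger. Demand
#' stays in prescription-equivalents here; conversion to head-counts happens
#' on the supply side of the sufficiency ratio.
#'
#' @inheritParams project_prescriptions
#' @param params A [parameter_set()] supplying `demand_coefficient`.
#' @return Prescription-equivalents per year.
#' @export
project_demand <- function(pop, rates, params, area, year) {
  if (!is.finite(params$demand_coefficient) || params$demand_coefficient <= 0) {
    stop("'demand_coefficient' must be > 0", call. = FALSE)
  }
  project_prescriptions(pop, rates, area, year) / params$demand_coefficient
}

#' Demand trajectory per area and overall
#'
#' Evaluates [project_demand()] over a contiguous range of years for every
#' area in the projection plus `"TOTAL"`. A normalized change-from-baseline
#' series (value divided by the first year's value, per area) is attached as
#' attribute `"change_from_baseline"`.
#'
#' @inheritParams project_demand
#' @param years Contiguous integer years, all covered by `pop`.
#' @return A [trajectory()] with unit `"prescription-equivalents/year"`.
#' @export
demand_trajectory <- function(pop, rates, params, years) {
  years <- as.integer(years)
  if (length(years) < 1 || !all(diff(years) == 1L)) {
    stop("'years' must be a contiguous range", call. = FALSE)
  }
  areas <- sort(unique(pop$area_id))
  grid <- expand.grid(area_id = c(areas, "TOTAL"), year = years,
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(a, y) project_demand(pop, rates, params, a, y),
                       grid$area_id, grid$year)
  traj <- trajectory(grid, unit = "prescription-equivalents/year")
  base <- traj[traj$year == years[1], c("area_id", "value")]
  names(base)[2] <- "baseline"
  norm <- dplyr::left_join(as.data.frame(traj), base, by = "area_id")
  norm$change <- ifelse(norm$baseline > 0, norm$value / norm$baseline, NA_real_)
  attr(traj, "change_from_baseline") <-
    tibble::as_tibble(norm[, c("area_id", "year", "change")])
  traj
}

#' Percent population change between two years
#'
#' `100 * (pop(to) - pop(from)) / pop(from)`, rounded to one decimal (the
#' convention of published projection tables).
#'
#' @param pop Either a `population_projection` (summed over age groups), or a
#'   data frame with columns `area_id` and per-year population columns named
#'   `pop_<year>` (the anchor-table layout of
#'   [hokkaido_population_anchors()]).
#' @param area Area id (or `"TOTAL"`; for anchor tables the printed `Total`
#'   row is used).
#' @param from_year,to_year Calendar years.
#' @return Signed percent change, one decimal.
#' @export
#' @examples
#' population_change(hokkaido_population_anchors(), "Total", 2015, 2025)
population_change <- function(pop, area, from_year, to_year) {
  get_total <- function(y) {
    if (inherits(pop, "population_projection")) {
      sum(pop_slice(pop, area, y))
    } else {
      col <- paste0("pop_", y)
      if (!col %in% names(pop)) {
        stop(sprintf("no population column for year %s", y), call. = FALSE)
      }
      id <- if (identical(area, "TOTAL")) "Total" else area
      row <- pop[pop$area_id == id, ]
      if (nrow(row) != 1) {
        stop(sprintf("area '%s' not found", area), call. = FALSE)
      }
      row[[col]]
    }
  }
  from <- get_total(from_year)
  to <- get_total(to_year)
  if (from == 0) stop("baseline population is zero", call. = FALSE)
  round(100 * (to - from) / from, 1)
}
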