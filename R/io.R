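#' @importFrom tibble tibble as_tibble
NULL

# 10 significant digits for every floating-point value written to disk,
# so golden-file comparisons and round-trips are stable across platforms.
fmt_num <- function(x) sprintf("%.10g", x)

#' Annual trajectories per area
#'
#' A trajectory is a tidy per-area, per-year series: supply head-counts
#' (unit `"persons"`), prescription capacity (`"prescriptions/year"`) or
#' demand (`"prescription-equivalents/year"`). The prefecture-wide series
#' uses the reserved area id `"TOTAL"`.
#'
#' @param df Data frame with columns `area_id`, `year`, `value`.
#' @param unit Unit string for all values.
#' @return A tibble of class `trajectory` with a `"unit"` attribute.
#' @export
trajectory <- function(df, unit) {
  stopifnot(all(c("area_id", "year", "value") %in% names(df)))
  out <- tibble::as_tibble(df[, c("area_id", "year", "value")])
  out$year <- as.integer(out$year)
  out$value <- as.numeric(out$value)
  attr(out, "unit") <- unit
  class(out) <- c("trajectory", class(out))
  out
}

#' @rdname trajectory
#' @param x A `trajectory`.
#' @export
trajectory_unit <- function(x) attr(x, "unit")

#' Write / read a trajectory as delimited text
#'
#' Columns `area_id, year, value, unit`; values are printed with 10
#' significant digits and round-trip through [read_trajectory()] exactly at
#' that precision.
#'
#' @param traj A non-empty `trajectory`.
#' @param path Output CSV path.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`: a
#'   `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) == 0) stop("cannot write an empty trajectory", call. = FALSE)
  df <- data.frame(
    area_id = traj$area_id,
    year = traj$year,
    value = fmt_num(traj$value),
    unit = trajectory_unit(traj),
    stringsAsFactors = FALSE
  )
  write_csv_checked(df, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("area_id", "year", "value", "unit")
  if (!identical(names(df), expected)) {
    stop(sprintf("trajectory file '%s' must have columns %s", path,
                 paste(expected, collapse = ",")), call. = FALSE)
  }
  unit <- unique(df$unit)
  if (length(unit) != 1) {
    stop("trajectory file mixes units", call. = FALSE)
  }
  trajectory(df, unit = unit)
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}

#' The standard 5-year age groups
#'
#' Eighteen bins: `0-4`, `5-9`, ..., `80-84`, `85+`.
#' @return Character vector of the ordered bin labels.
#' @export
age_groups_5yr <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

#' Population projections by area, year and age group
#'
#' @param df Data frame with columns `area_id`, `year`, `age_group`,
#'   `persons`. Every (area, year) cell must carry the complete set of age
#'   groups and all counts must be non-negative.
#' @param age_groups Ordered age-bin labels.
#' @return A tibble of class `population_projection` with attribute
#'   `"age_groups"`.
#' @export
population_projection <- function(df, age_groups = age_groups_5yr()) {
  stopifnot(all(c("area_id", "year", "age_group", "persons") %in% names(df)))
  out <- tibble::as_tibble(df[, c("area_id", "year", "age_group", "persons")])
  out$year <- as.integer(out$year)
  out$persons <- as.numeric(out$persons)
  if (any(out$persons < 0)) stop("population counts must be >= 0", call. = FALSE)
  bad <- setdiff(unique(out$age_group), age_groups)
  if (length(bad)) {
    stop(sprintf("unknown age group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  counts <- table(out$area_id, out$year)
  if (any(counts != length(age_groups))) {
    stop("every (area, year) must have a complete set of age groups",
         call. = FALSE)
  }
  attr(out, "age_groups") <- age_groups
  class(out) <- c("population_projection", class(out))
  out
}

#' @rdname population_projection
#' @param path CSV with columns `area_id,year,age_group,persons`.
#' @export
read_population <- function(path) {
  population_projection(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname population_projection
#' @param pop A `population_projection`.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population_projection"))
  df <- as.data.frame(pop)
  df$persons <- fmt_num(df$persons)
  write_csv_checked(df, path)
  invisible(path)
}

#' Age-specific prescription rates
#'
#' Prescriptions per person per year for each 5-year age group.
#'
#' @param rates Named numeric vector (names are age-group labels) or a data
#'   frame with columns `age_group`, `prescriptions_per_person_year`.
#' @return Named numeric vector of class `age_rates`.
#' @export
age_rates <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("age_group", "prescriptions_per_person_year") %in%
                    names(rates)))
    rates <- stats::setNames(as.numeric(rates$prescriptions_per_person_year),
                             rates$age_group)
  }
  if (is.null(names(rates))) stop("rates must be named by age group",
                                  call. = FALSE)
  if (any(rates < 0)) stop("prescription rates must be >= 0", call. = FALSE)
  structure(as.numeric(stats::setNames(rates, names(rates))),
            names = names(rates), class = "age_rates")
}

#' @rdname age_rates
#' @param path CSV with columns `age_group,prescriptions_per_person_year`.
#' @export
read_rates <- function(path) {
  age_rates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname age_rates
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "age_rates"))
  df <- data.frame(age_group = names(rates),
                   prescriptions_per_person_year = fmt_num(unclass(rates)),
                   stringsAsFactors = FALSE)
  write_csv_checked(df, path)
  invisible(path)
}

#' Read / write diffusion shares and historical head-counts
#'
#' `read_shares()` reads an `area_id,share` CSV into a named vector (pass it
#' through [diffusion_shares()] to validate); `write_shares()` is its
#' inverse. `read_history()` reads a `year,pharmacists` CSV into a `TOTAL`
#' trajectory in persons; `write_history()` is its inverse.
#'
#' @param path CSV path.
#' @return See details above.
#' @export
read_shares <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("area_id", "share"))) {
    stop(sprintf("shares file '%s' must have columns area_id,share", path),
         call. = FALSE)
  }
  stats::setNames(as.numeric(df$share), df$area_id)
}

#' @rdname read_shares
#' @param shares A `diffusion_shares` (or named vector).
#' @export
write_shares <- function(shares, path) {
  df <- data.frame(area_id = names(shares), share = fmt_num(as.numeric(shares)),
                   stringsAsFactors = FALSE)
  write_csv_checked(df, path)
  invisible(path)
}

#' @rdname read_shares
#' @export
read_history <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("year", "pharmacists"))) {
    stop(sprintf("history file '%s' must have columns year,pharmacists", path),
         call. = FALSE)
  }
  trajectory(data.frame(area_id = "TOTAL", year = df$year,
                        value = df$pharmacists),
             unit = "persons")
}

#' @rdname read_shares
#' @param traj A `TOTAL` trajectory in persons.
#' @export
write_history <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  tot <- traj[traj$area_id == "TOTAL", ]
  df <- data.frame(year = tot$year, pharmacists = fmt_num(tot$value))
  write_csv_checked(df, path)
  invisible(path)
}
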