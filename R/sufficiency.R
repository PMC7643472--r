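#' Convert a pharmacist head-count to annual prescription capacity
#'
#' `headcount * prescriptions_per_pharmacist_per_day * working_days_per_year`.
#' The per-day rate is itself defined as total prescriptions divided by the
#' pharmacist head-count and by the working days per year, so this is the
#' exact inverse of [per_pharmacist_per_day()].
#'
#' @param headcount Pharmacists (full-time-equivalent head-count), >= 0.
#' @param params A [parameter_set()].
#' @return Prescriptions per year.
#' @export
#' @examples
#' supply_capacity(1, parameter_set())  # 17.64 * 253.8
supply_capacity <- function(headcount, params) {
  if (any(headcount < 0)) stop("headcount must be >= 0", call. = FALSE)
  headcount * params$prescriptions_per_pharmacist_per_day *
    params$working_days_per_year
}

#' @rdname supply_capacity
#' @param total_prescriptions Prescriptions per year.
#' @param n_pharmacists Pharmacists (> 0).
#' @param working_days Working days per year (> 0).
#' @export
per_pharmacist_per_day <- function(total_prescriptions, n_pharmacists,
                                   working_days) {
  if (any(n_pharmacists <= 0) || any(working_days <= 0)) {
    stop("pharmacist count and working days must be > 0", call. = FALSE)
  }
  total_prescriptions / n_pharmacists / working_days
}

#' Supply/demand sufficiency ratio
#'
#' Supply capacity divided by demand, both in prescription-equivalent units.
#' Ratios above 1 mean supply surpasses demand. Zero demand makes the ratio
#' undefined and is reported as `NA`, never infinity.
#'
#' @param supply Prescriptions per year (capacity).
#' @param demand Prescription-equivalents per year.
#' @return Dimensionless ratio (vectorized); `NA` where `demand == 0`.
#' @export
sufficiency_ratio <- function(supply, demand) {
  ifelse(demand > 0, supply / demand, NA_real_)
}

#' Build a sufficiency report from supply and demand trajectories
#'
#' Converts a head-count supply trajectory to prescription capacity (a
#' capacity trajectory is used as-is), joins it with the demand trajectory
#' on (area, year), and flags shortages (`ratio < 1`) and surpluses
#' (`ratio >= 2`). The demand coefficient enters only on the demand side;
#' capacity is never divided by it.
#'
#' @param supply_traj A [trajectory()] in `"persons"` or
#'   `"prescriptions/year"`.
#' @param demand_traj A [trajectory()] in `"prescription-equivalents/year"`
#'   covering the same (area, year) cells.
#' @param params A [parameter_set()].
#' @return A tibble of class `sufficiency_report` with columns
#'   `area_id, year, supply, demand, ratio, flag`
#'   (`flag` in `"shortage"`, `"ok"`, `"surplus"`, `"undefined"`).
#' @export
build_report <- function(supply_traj, demand_traj, params) {
  stopifnot(inherits(supply_traj, "trajectory"),
            inherits(demand_traj, "trajectory"))
  s <- as.data.frame(supply_traj)
  if (identical(trajectory_unit(supply_traj), "persons")) {
    s$value <- supply_capacity(s$value, params)
  }
  d <- as.data.frame(demand_traj)
  key_s <- paste(s$area_id, s$year)
  key_d <- paste(d$area_id, d$year)
  only_s <- setdiff(key_s, key_d)
  only_d <- setdiff(key_d, key_s)
  if (length(only_s) || length(only_d)) {
    stop(sprintf(
      "supply and demand trajectories do not align; supply-only: [%s], demand-only: [%s]",
      paste(only_s, collapse = "; "), paste(only_d, collapse = "; ")),
      call. = FALSE)
  }
  names(s)[names(s) == "value"] <- "supply"
  names(d)[names(d) == "value"] <- "demand"
  rep <- dplyr::inner_join(s, d, by = c("area_id", "year"))
  rep$ratio <- sufficiency_ratio(rep$supply, rep$demand)
  rep$flag <- ifelse(is.na(rep$ratio), "undefined",
                     ifelse(rep$ratio < 1, "shortage",
                            ifelse(rep$ratio >= 2, "surplus", "ok")))
  rep <- tibble::as_tibble(rep)
  class(rep) <- c("sufficiency_report", class(rep))
  rep
}

#' Backtest a projection against published head-counts
#'
#' Relative root-mean-squared error over the overlapping years:
#' `RMSE = sqrt( mean( (|actual_t - projected_t| / projected_t)^2 ) )`.
#' Note the convention: the denominator is the *projected* value. A model
#' passes the behavior test when RMSE does not exceed the threshold
#' (0.1 by convention for stock-flow projection models).
#'
#' @param projected,actual `TOTAL`-bearing [trajectory()] objects in
#'   persons (compared on the intersection of their (area, year) cells).
#' @param threshold Pass/fail RMSE threshold.
#' @return A list of class `validation_report`: `rmse`, `n`,
#'   `per_year_relative_error` (named by year; signed errors
#'   `(actual - projected) / projected`), `passed`, `threshold`.
#' @export
rmse_backtest <- function(projected, actual, threshold = 0.1) {
  stopifnot(inherits(projected, "trajectory"), inherits(actual, "trajectory"))
  p <- as.data.frame(projected)
  a <- as.data.frame(actual)
  names(p)[names(p) == "value"] <- "projected"
  names(a)[names(a) == "value"] <- "actual"
  m <- dplyr::inner_join(p, a, by = c("area_id", "year"))
  if (nrow(m) == 0) stop("no overlapping (area, year) cells", call. = FALSE)
  if (any(m$projected == 0)) {
    stop("projected values of zero cannot enter the relative error",
         call. = FALSE)
  }
  rel <- (m$actual - m$projected) / m$projected
  rmse <- sqrt(mean(rel^2))
  structure(
    list(rmse = rmse,
         n = nrow(m),
         per_year_relative_error = stats::setNames(rel, m$year),
         passed = rmse <= threshold,
         threshold = threshold),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> rmse = %.6g over %d year(s); %s (threshold %.3g)\n",
              x$rmse, x$n, if (x$passed) "PASSED" else "FAILED", x$threshold))
  invisible(x)
}
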