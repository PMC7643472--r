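#' State of the pharmacist career-path pipeline
#'
#' Stocks at one point in time: students by program year (year 1 is the
#' newest cohort), the pool of committed exam re-takers, graduate students by
#' program year, and the pharmacist head-count per medical area. All stocks
#' are real-valued person counts; fractional persons are carried unrounded
#' throughout the simulation.
#'
#' @param params A [parameter_set()] (fixes the vector lengths).
#' @param students Numeric vector of length `education_years`.
#' @param retakers Scalar committed re-taker pool (failers who will re-sit
#'   the exam next year).
#' @param gradschool Numeric vector of length `gradschool_years`.
#' @param pharmacists Named numeric vector of per-area stocks.
#' @return An object of class `pipeline_state`.
#' @export
#' @examples
#' st <- pipeline_state(parameter_set(), pharmacists = c(Sapporo = 3039))
pipeline_state <- function(params,
                           students = rep(0, params$education_years),
                           retakers = 0,
                           gradschool = rep(0, params$gradschool_years),
                           pharmacists = numeric(0)) {
  stopifnot(length(students) == params$education_years,
            length(gradschool) == params$gradschool_years,
            length(retakers) == 1)
  if (any(students < 0) || retakers < 0 || any(gradschool < 0) ||
      any(pharmacists < 0)) {
    stop("pipeline stocks must be >= 0", call. = FALSE)
  }
  structure(
    list(students = as.numeric(students),
         retakers = as.numeric(retakers),
         gradschool = as.numeric(gradschool),
         pharmacists = pharmacists),
    class = "pipeline_state"
  )
}

#' @export
print.pipeline_state <- function(x, ...) {
  cat("<pipeline_state>\n")
  cat("  students (year 1..n): ", paste(round(x$students, 2), collapse = ", "),
      "\n")
  cat("  retakers:             ", round(x$retakers, 2), "\n")
  cat("  gradschool (yr 1..n): ", paste(round(x$gradschool, 2), collapse = ", "),
      "\n")
  cat("  pharmacists:          ", length(x$pharmacists), "area(s), total",
      round(sum(x$pharmacists), 2), "\n")
  invisible(x)
}

#' Advance the career-path pipeline by one year
#'
#' One discrete annual step of the stock-flow model,
#' `stock(t+1) = stock(t) + inflow - outflow`. Within the year, flows are
#' applied in a fixed order: (1) final-year students graduate and sit the
#' exam (`takers = final * g * x`); (2) first-time passes `takers * q1`;
#' failers commit to a re-take with probability `r` and join the pool, the
#' rest exit; (3) the committed pool sits the exam, passing at rate `q2`;
#' failers re-commit with probability `r`, the rest exit; (4) a fraction `s`
#' of fresh-graduate passers enters graduate school; of the remaining passers
#' (fresh and re-take alike) a fraction `c` chooses pharmacies, the rest go
#' to hospitals/industry; (5) graduate-school finishers contribute fraction
#' `w` to pharmacies; (6) the year's new pharmacy pharmacists are allocated
#' across areas by the diffusion shares (negative shares are net outflows;
#' any stock pushed below zero is clamped to 0 and the shortfall logged, not
#' redistributed); (7) attrition removes fraction `a` of every area stock;
#' (8) students and graduate students advance one program year and the new
#' enrollment cohort enters year 1.
#'
#' @param state A [pipeline_state()].
#' @param params A [parameter_set()].
#' @param shares A [diffusion_shares()] over the areas of
#'   `state$pharmacists` (ignored when the state has no areas).
#' @return A list with elements `state` (the advanced `pipeline_state`) and
#'   `flows` (named numeric log of every flow magnitude for the year).
#' @export
step_pipeline <- function(state, params, shares = NULL) {
  p <- params
  if (length(state$pharmacists) > 0) {
    if (is.null(shares)) stop("shares are required when areas are present",
                              call. = FALSE)
    if (!setequal(names(shares), names(state$pharmacists))) {
      stop("share areas do not match state areas", call. = FALSE)
    }
  }

  final <- state$students[p$education_years]
  takers <- final * p$graduation_rate * p$examination_rate
  first_pass <- takers * p$pass_rate_first
  new_fails <- takers * (1 - p$pass_rate_first)

  retaker_pass <- state$retakers * p$pass_rate_retake
  retaker_fail <- state$retakers * (1 - p$pass_rate_retake)
  retaker_recommit <- retaker_fail * p$reexamination_rate
  new_commit <- new_fails * p$reexamination_rate
  retake_exit <- retaker_fail * (1 - p$reexamination_rate) +
    new_fails * (1 - p$reexamination_rate)

  gs_entry <- first_pass * p$gradschool_entry_rate
  employable <- (first_pass - gs_entry) + retaker_pass
  to_pharmacy_exam <- employable * p$pharmacy_choice_rate
  other_exit <- employable * (1 - p$pharmacy_choice_rate)

  gs_finish <- state$gradschool[p$gradschool_years]
  gs_to_pharmacy <- gs_finish * p$gradschool_to_pharmacy_rate
  new_pharmacists <- to_pharmacy_exam + gs_to_pharmacy

  pharm <- state$pharmacists
  clamp_shortfall <- 0
  attrition_loss <- 0
  if (length(pharm) > 0) {
    pharm <- pharm + new_pharmacists * as.numeric(shares)[match(names(pharm),
                                                                names(shares))]
    below <- pharm < 0
    clamp_shortfall <- -sum(pharm[below])
    pharm[below] <- 0
    attrition_loss <- sum(pharm) * p$attrition_rate
    pharm <- pharm * (1 - p$attrition_rate)
  }

  students <- c(p$enrollments, state$students[-p$education_years])
  gradschool <- c(gs_entry,
                  state$gradschool[-p$gradschool_years])
  retakers <- new_commit + retaker_recommit

  new_state <- pipeline_state(p, students = students, retakers = retakers,
                              gradschool = gradschool, pharmacists = pharm)
  flows <- c(
    takers = takers,
    first_pass = first_pass,
    new_fails = new_fails,
    retaker_pass = retaker_pass,
    retaker_recommit = retaker_recommit,
    new_commit = new_commit,
    retake_exit = retake_exit,
    non_exam_exit = state$students[p$education_years] - takers,
    gradschool_entry = gs_entry,
    gradschool_finish = gs_finish,
    gradschool_to_pharmacy = gs_to_pharmacy,
    to_pharmacy_exam = to_pharmacy_exam,
    other_workplace_exit = other_exit,
    new_pharmacists = new_pharmacists,
    clamp_shortfall = clamp_shortfall,
    attrition_loss = attrition_loss
  )
  list(state = new_state, flows = flows)
}

#' Newly licensed pharmacists recorded in a flow log
#'
#' First-time plus re-take exam passes for the year.
#'
#' @param flows The `flows` element returned by [step_pipeline()].
#' @return Persons per year (non-negative scalar).
#' @export
annual_new_licensees <- function(flows) {
  unname(flows[["first_pass"]] + flows[["retaker_pass"]])
}

#' Steady-state education pipeline under constant enrollment
#'
#' Iterates the student/re-taker/graduate-school recurrences (pharmacist
#' stocks held at zero) under constant enrollment until no pipeline stock
#' changes by more than 1e-10 between years. The caller sets
#' `pharmacists` afterwards, from an area table.
#'
#' @param params A [parameter_set()].
#' @param max_iter Iteration cap; non-convergence is an error (cannot occur
#'   for rates in `[0, 1)`).
#' @return A converged `pipeline_state` with zero pharmacist stocks.
#' @export
warm_up_pipeline <- function(params, max_iter = 1000L) {
  st <- pipeline_state(params)
  for (i in seq_len(max_iter)) {
    nxt <- step_pipeline(st, params, shares = NULL)$state
    delta <- max(abs(nxt$students - st$students),
                 abs(nxt$retakers - st$retakers),
                 abs(nxt$gradschool - st$gradschool))
    st <- nxt
    if (delta < 1e-10) return(st)
  }
  stop("pipeline warm-up did not converge", call. = FALSE)
}

#' Simulate the pharmacist supply over a horizon
#'
#' Runs [step_pipeline()] for `horizon` years from `start_year` and collects
#' the per-area head-count series plus the prefecture-wide `TOTAL` row. The
#' value at `start_year` is the initial stock; subsequent years are the
#' post-step stocks.
#'
#' @param initial A [pipeline_state()] with per-area pharmacist stocks set.
#' @param params A [parameter_set()].
#' @param shares A [diffusion_shares()] over the same areas.
#' @param start_year First calendar year of the series.
#' @param horizon Number of simulated years (>= 1).
#' @return A [trajectory()] in persons covering
#'   `start_year:(start_year + horizon)`, with the per-year flow log attached
#'   as attribute `"flow_log"` (a tibble, one row per simulated year).
#' @export
#' @examples
#' p <- parameter_set()
#' st <- warm_up_pipeline(p)
#' st$pharmacists <- c(Sapporo = 3039, Tokachi = 343)
#' sh <- diffusion_shares(c(Sapporo = 0.9, Tokachi = 0.1))
#' simulate_supply(st, p, sh, 2015, 5)
simulate_supply <- function(initial, params, shares, start_year, horizon) {
  if (length(horizon) != 1 || is.na(horizon) || horizon < 1) {
    stop("'horizon' must be >= 1", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  areas <- names(initial$pharmacists)
  years <- seq(start_year, start_year + horizon)

  snapshot <- function(st, yr) {
    tibble::tibble(
      area_id = c(areas, "TOTAL"),
      year = as.integer(yr),
      value = c(unname(st$pharmacists), sum(st$pharmacists))
    )
  }

  rows <- vector("list", horizon + 1L)
  logs <- vector("list", horizon)
  st <- initial
  rows[[1]] <- snapshot(st, years[1])
  for (k in seq_len(horizon)) {
    out <- step_pipeline(st, params, shares)
    st <- out$state
    rows[[k + 1L]] <- snapshot(st, years[k + 1L])
    logs[[k]] <- tibble::as_tibble(c(list(year = years[k + 1L]),
                                     as.list(out$flows)))
  }
  traj <- trajectory(dplyr::bind_rows(rows), unit = "persons")
  attr(traj, "flow_log") <- dplyr::bind_rows(logs)
  traj
}

#' @rdname simulate_supply
#' @param traj A trajectory returned by `simulate_supply()`.
#' @export
flow_log <- function(traj) attr(traj, "flow_log")
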