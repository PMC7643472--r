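#' Model parameters for the pharmacist supply/demand projection
#'
#' Bundles every lever of the career-path supply model and the
#' prescription-based demand/sufficiency calculations. Defaults are the
#' Hokkaido base-case values: mean annual enrollments across the three
#' pharmacy faculties, graduation/examination/pass rates of the national
#' licensure exam (first attempt and re-take), the share of passers choosing
#' pharmacies over hospitals and industry, graduate-school entry and
#' return-to-pharmacy rates, and the annual attrition of the pharmacist
#' stock. The sufficiency constants convert head-counts to prescription
#' capacity (prescriptions handled per pharmacist per day, working days per
#' year) and prescription volume to total-work demand (the demand
#' coefficient: the ~80% share of pharmacist work time spent on
#' prescription-related tasks).
#'
#' @param enrollments Persons entering the education pipeline per year.
#' @param graduation_rate Fraction of an enrollment cohort graduating on time.
#' @param examination_rate Fraction of graduates sitting the national exam.
#' @param reexamination_rate Fraction of failers who re-take the exam the
#'   following year.
#' @param pass_rate_first First-attempt national exam pass rate.
#' @param pass_rate_retake Pass rate on re-examination.
#' @param pharmacy_choice_rate Fraction of new licensees choosing pharmacies
#'   as their workplace.
#' @param gradschool_entry_rate Fraction of fresh graduates entering graduate
#'   school after graduation.
#' @param gradschool_to_pharmacy_rate Fraction of graduate-school finishers
#'   employed in pharmacies.
#' @param attrition_rate Annual fractional loss of the pharmacist stock from
#'   all causes (quitting, death).
#' @param education_years Length of the pharmacy degree, years.
#' @param gradschool_years Length of graduate school, years.
#' @param prescriptions_per_pharmacist_per_day Average prescriptions one
#'   pharmacist handles per working day.
#' @param working_days_per_year Average working days per year.
#' @param demand_coefficient Fraction of pharmacist work time spent on
#'   prescription-related tasks; divides prescription volume to give
#'   total-work demand.
#'
#' @return An object of class `parameter_set`: a validated named list.
#' @export
#' @examples
#' p <- parameter_set()
#' p$pass_rate_first
#' parameter_set(attrition_rate = 0.012)$attrition_rate
parameter_set <- function(enrollments = 399.824,
                          graduation_rate = 0.962,
                          examination_rate = 0.803,
                          reexamination_rate = 0.963,
                          pass_rate_first = 0.738,
                          pass_rate_retake = 0.593,
                          pharmacy_choice_rate = 0.458,
                          gradschool_entry_rate = 0.025,
                          gradschool_to_pharmacy_rate = 0.39,
                          attrition_rate = 0.007,
                          education_years = 6L,
                          gradschool_years = 4L,
                          prescriptions_per_pharmacist_per_day = 17.64,
                          working_days_per_year = 253.8,
                          demand_coefficient = 0.8) {
  p <- list(
    enrollments = as.numeric(enrollments),
    graduation_rate = as.numeric(graduation_rate),
    examination_rate = as.numeric(examination_rate),
    reexamination_rate = as.numeric(reexamination_rate),
    pass_rate_first = as.numeric(pass_rate_first),
    pass_rate_retake = as.numeric(pass_rate_retake),
    pharmacy_choice_rate = as.numeric(pharmacy_choice_rate),
    gradschool_entry_rate = as.numeric(gradschool_entry_rate),
    gradschool_to_pharmacy_rate = as.numeric(gradschool_to_pharmacy_rate),
    attrition_rate = as.numeric(attrition_rate),
    education_years = as.integer(education_years),
    gradschool_years = as.integer(gradschool_years),
    prescriptions_per_pharmacist_per_day =
      as.numeric(prescriptions_per_pharmacist_per_day),
    working_days_per_year = as.numeric(working_days_per_year),
    demand_coefficient = as.numeric(demand_coefficient)
  )
  class(p) <- "parameter_set"
  validate_parameter_set(p)
}

#' @rdname parameter_set
#' @param x Object to validate.
#' @export
validate_parameter_set <- function(x) {
  stopifnot(inherits(x, "parameter_set"))
  rates <- c(
    "graduation_rate", "examination_rate", "reexamination_rate",
    "pass_rate_first", "pass_rate_retake", "pharmacy_choice_rate",
    "gradschool_entry_rate", "gradschool_to_pharmacy_rate", "attrition_rate"
  )
  for (r in rates) {
    v <- x[[r]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("parameter '%s' must lie in [0, 1], got %s", r, format(v)),
           call. = FALSE)
    }
  }
  if (!is.finite(x$enrollments) || x$enrollments < 0) {
    stop("'enrollments' must be >= 0", call. = FALSE)
  }
  if (is.na(x$education_years) || x$education_years < 1L) {
    stop("'education_years' must be a positive integer", call. = FALSE)
  }
  if (is.na(x$gradschool_years) || x$gradschool_years < 1L) {
    stop("'gradschool_years' must be a positive integer", call. = FALSE)
  }
  if (!is.finite(x$demand_coefficient) || x$demand_coefficient <= 0 ||
      x$demand_coefficient > 1) {
    stop("'demand_coefficient' must lie in (0, 1]", call. = FALSE)
  }
  for (f in c("prescriptions_per_pharmacist_per_day", "working_days_per_year")) {
    if (!is.finite(x[[f]]) || x[[f]] <= 0) {
      stop(sprintf("'%s' must be > 0", f), call. = FALSE)
    }
  }
  x
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-38s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Read a parameter set from a flat YAML/JSON config file
#'
#' Keys are the `parameter_set()` argument names; missing keys take the
#' base-case defaults, unknown keys are an error (fail-fast), and every value
#' is validated (rates must lie in `[0, 1]`).
#'
#' @param path Path to a YAML (or JSON) file with a flat key/value mapping.
#'   An empty file yields the full default set.
#' @return A `parameter_set`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("failed to parse config '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop(sprintf("config '%s' must be a flat key/value mapping", path),
         call. = FALSE)
  }
  known <- names(formals(parameter_set))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(parameter_set, cfg)
}
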