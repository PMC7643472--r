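# Independent plain-recurrence oracle for the career-path simulator.
# Deliberately coded as bare scalar recurrences (no package internals) so it
# can serve as a second route for equivalence tests.
oracle_supply <- function(params, shares, students, retakers, gradschool,
                          pharmacists, horizon) {
  E <- params$enrollments
  g <- params$graduation_rate
  x <- params$examination_rate
  r <- params$reexamination_rate
  q1 <- params$pass_rate_first
  q2 <- params$pass_rate_retake
  cc <- params$pharmacy_choice_rate
  s <- params$gradschool_entry_rate
  w <- params$gradschool_to_pharmacy_rate
  a <- params$attrition_rate

  sh <- as.numeric(shares)[match(names(pharmacists), names(shares))]
  snapshots <- matrix(NA_real_, nrow = horizon + 1, ncol = length(pharmacists),
                      dimnames = list(NULL, names(pharmacists)))
  snapshots[1, ] <- pharmacists
  for (t in seq_len(horizon)) {
    takers <- students[length(students)] * g * x
    pass1 <- takers * q1
    passR <- retakers * q2
    pool <- takers * (1 - q1) * r + retakers * (1 - q2) * r
    gs_in <- pass1 * s
    inflow <- ((pass1 - gs_in) + passR) * cc + gradschool[length(gradschool)] * w
    pharmacists <- pharmacists + inflow * sh
    pharmacists[pharmacists < 0] <- 0
    pharmacists <- pharmacists * (1 - a)
    students <- c(E, students[-length(students)])
    gradschool <- c(gs_in, gradschool[-length(gradschool)])
    retakers <- pool
    snapshots[t + 1, ] <- pharmacists
  }
  snapshots
}

# Closed form for the eventual pass fraction of one cohort of exam takers
# through the re-take loop.
eventual_pass_fraction <- function(q1, r, q2) {
  q1 + (1 - q1) * r * q2 / (1 - r * (1 - q2))
}

# A tiny two-area baseline for experiment tests: flat synthetic population,
# modest aging, deterministic.
toy_baseline <- function(seed = 42, noise_sd = 0, start_year = 2015,
                         end_year = 2040) {
  params <- parameter_set()
  cfg <- synth_config(seed = seed, noise_sd = noise_sd,
                      start_year = start_year, end_year = end_year)
  gen_baseline_calibrated(cfg, target_ratio = 1.19, params = params)
}

random_params <- function() {
  parameter_set(
    enrollments = stats::runif(1, 0, 500),
    graduation_rate = stats::runif(1),
    examination_rate = stats::runif(1),
    reexamination_rate = stats::runif(1),
    pass_rate_first = stats::runif(1),
    pass_rate_retake = stats::runif(1),
    pharmacy_choice_rate = stats::runif(1),
    gradschool_entry_rate = stats::runif(1),
    gradschool_to_pharmacy_rate = stats::runif(1),
    attrition_rate = stats::runif(1)
  )
}

flat_population <- function(areas = c("A", "B"), years = 2015:2020,
                            persons = 1000) {
  grid <- expand.grid(area_id = areas, year = years,
                      age_group = age_groups_5yr(), stringsAsFactors = FALSE)
  grid$persons <- persons
  population_projection(grid)
}
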