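test_that("null dynamics leave the state unchanged apart from the zero shift", {
  p <- parameter_set(enrollments = 0, graduation_rate = 0,
                     examination_rate = 0, reexamination_rate = 0,
                     pass_rate_first = 0, pass_rate_retake = 0,
                     pharmacy_choice_rate = 0, gradschool_entry_rate = 0,
                     gradschool_to_pharmacy_rate = 0, attrition_rate = 0)
  st <- pipeline_state(p, pharmacists = c(A = 10))
  out <- step_pipeline(st, p, diffusion_shares(c(A = 1)))
  expect_equal(out$state$students, rep(0, 6))
  expect_equal(out$state$retakers, 0)
  expect_equal(out$state$pharmacists, c(A = 10))
  expect_equal(annual_new_licensees(out$flows), 0)
})

test_that("a lossless cohort arrives in the pharmacist stock after the education delay", {
  p <- parameter_set(enrollments = 0, graduation_rate = 1,
                     examination_rate = 1, pass_rate_first = 1,
                     pharmacy_choice_rate = 1, gradschool_entry_rate = 0,
                     attrition_rate = 0)
  st <- pipeline_state(p, students = c(100, 0, 0, 0, 0, 0),
                       pharmacists = c(A = 0))
  sh <- diffusion_shares(c(A = 1))
  for (k in seq_len(p$education_years)) {
    out <- step_pipeline(st, p, sh)
    st <- out$state
    if (k == p$education_years) {
      expect_equal(annual_new_licensees(out$flows), 100)
    } else {
      expect_equal(annual_new_licensees(out$flows), 0)
    }
  }
  expect_equal(unname(st$pharmacists["A"]), 100)
})

test_that("the re-take loop reproduces its geometric-series closed form", {
  p <- parameter_set()
  # one cohort of 100 exam takers, no re-entry: place it so takers = 100
  students <- rep(0, 6)
  students[6] <- 100 / (p$graduation_rate * p$examination_rate)
  pp <- p
  pp$enrollments <- 0
  st <- pipeline_state(pp, students = students, pharmacists = c(A = 0))
  sh <- diffusion_shares(c(A = 1))
  total_pass <- 0
  for (k in 1:250) {
    out <- step_pipeline(st, pp, sh)
    st <- out$state
    total_pass <- total_pass + annual_new_licensees(out$flows)
  }
  expect_equal(total_pass,
               100 * eventual_pass_fraction(p$pass_rate_first,
                                            p$reexamination_rate,
                                            p$pass_rate_retake),
               tolerance = 1e-9)
})

test_that("cohort conservation: passers plus exits equal the enrollment", {
  p <- parameter_set(attrition_rate = 0)
  pp <- p
  pp$enrollments <- 0
  E <- 250
  st <- pipeline_state(pp, students = c(E, 0, 0, 0, 0, 0),
                       pharmacists = c(A = 0))
  sh <- diffusion_shares(c(A = 1))
  passers <- 0
  exits <- 0
  for (k in 1:250) {
    out <- step_pipeline(st, pp, sh)
    st <- out$state
    passers <- passers + annual_new_licensees(out$flows)
    exits <- exits + out$flows[["non_exam_exit"]] + out$flows[["retake_exit"]]
  }
  expect_equal(passers + exits, E, tolerance = 1e-9 * E)
})

test_that("warm-up reaches the steady state of the cohort recurrences", {
  p <- parameter_set()
  st <- warm_up_pipeline(p)
  expect_equal(st$students, rep(p$enrollments, 6))
  takers <- p$enrollments * p$graduation_rate * p$examination_rate
  expect_equal(st$retakers,
               takers * (1 - p$pass_rate_first) * p$reexamination_rate /
                 (1 - p$reexamination_rate * (1 - p$pass_rate_retake)),
               tolerance = 1e-9)
  expect_equal(st$gradschool,
               rep(takers * p$pass_rate_first * p$gradschool_entry_rate, 4),
               tolerance = 1e-9)
  expect_equal(sum(st$pharmacists), 0)

  expect_equal(warm_up_pipeline(parameter_set(enrollments = 0))$students,
               rep(0, 6))
  nofail <- warm_up_pipeline(parameter_set(graduation_rate = 1,
                                           examination_rate = 1,
                                           pass_rate_first = 1))
  expect_equal(nofail$students[6], 399.824)
  expect_equal(nofail$retakers, 0)
})

test_that("steady-state annual licensees match the closed form", {
  p <- parameter_set()
  st <- warm_up_pipeline(p)
  st$pharmacists <- c(A = 0)
  out <- step_pipeline(st, p, diffusion_shares(c(A = 1)))
  expected <- p$enrollments * p$graduation_rate * p$examination_rate *
    eventual_pass_fraction(p$pass_rate_first, p$reexamination_rate,
                           p$pass_rate_retake)
  expect_equal(annual_new_licensees(out$flows), expected, tolerance = 0.5)
  expect_equal(expected, 304, tolerance = 1)
})

test_that("attrition-only dynamics decay analytically", {
  p <- parameter_set(enrollments = 0, attrition_rate = 0.03)
  st <- pipeline_state(p, pharmacists = c(A = 5000))
  traj <- simulate_supply(st, p, diffusion_shares(c(A = 1)), 2015, 20)
  tot <- traj[traj$area_id == "TOTAL", ]
  expect_equal(tot$value, 5000 * (1 - 0.03)^(0:20), tolerance = 1e-12)
})

test_that("simulate_supply validates the horizon and handles empty states", {
  p <- parameter_set()
  st <- pipeline_state(p, pharmacists = c(A = 0))
  sh <- diffusion_shares(c(A = 1))
  expect_error(simulate_supply(st, p, sh, 2015, 0), "horizon")
  tr <- simulate_supply(pipeline_state(parameter_set(enrollments = 0),
                                       pharmacists = c(A = 0)),
                        parameter_set(enrollments = 0), sh, 2015, 1)
  expect_true(all(tr$value == 0))
})

test_that("the TOTAL series is the sum of the area series everywhere", {
  p <- parameter_set()
  st <- warm_up_pipeline(p)
  areas <- hokkaido_areas()
  st$pharmacists <- stats::setNames(as.numeric(areas$pharmacists),
                                    areas$area_id)
  traj <- simulate_supply(st, p, hokkaido_shares("base"), 2015, 25)
  by_year <- tapply(traj$value[traj$area_id != "TOTAL"],
                    traj$year[traj$area_id != "TOTAL"], sum)
  tot <- traj$value[traj$area_id == "TOTAL"]
  expect_equal(
    as.numeric(by_year[as.character(traj$year[traj$area_id == "TOTAL"])]),
    tot, tolerance = 1e-9)
})

test_that("negative shares clamp stocks at zero and log the shortfall", {
  p <- parameter_set(enrollments = 0, attrition_rate = 0)
  st <- pipeline_state(p, students = c(0, 0, 0, 0, 0, 1000),
                       pharmacists = c(A = 5, B = 0))
  pp <- parameter_set(enrollments = 0, attrition_rate = 0,
                      graduation_rate = 1, examination_rate = 1,
                      pass_rate_first = 1, pharmacy_choice_rate = 1,
                      gradschool_entry_rate = 0)
  st <- pipeline_state(pp, students = c(0, 0, 0, 0, 0, 1000),
                       pharmacists = c(A = 5, B = 0))
  out <- step_pipeline(st, pp, diffusion_shares(c(A = -0.01, B = 1.01)))
  expect_equal(unname(out$state$pharmacists["A"]), 0)
  expect_equal(out$flows[["clamp_shortfall"]], 5, tolerance = 1e-9)
  expect_gt(unname(out$state$pharmacists["B"]), 1000)
})

test_that("supply is monotone in enrollments and pass rate, antitone in attrition", {
  areas <- c(A = 3000, B = 500)
  sh <- diffusion_shares(c(A = 0.8, B = 0.2))
  total_series <- function(params) {
    st <- warm_up_pipeline(params)
    st$pharmacists <- areas
    tr <- simulate_supply(st, params, sh, 2015, 25)
    tr$value[tr$area_id == "TOTAL"]
  }
  base <- total_series(parameter_set())
  expect_true(all(total_series(parameter_set(enrollments = 440)) >= base))
  expect_true(all(total_series(parameter_set(enrollments = 360)) <= base))
  expect_true(all(total_series(parameter_set(pass_rate_first = 0.838,
                                             pass_rate_retake = 0.693)) >= base))
  expect_true(all(total_series(parameter_set(attrition_rate = 0.012)) <= base))
  expect_true(all(total_series(parameter_set(attrition_rate = 0.002)) >= base))
})

test_that("the simulator agrees with the independent recurrence oracle", {
  set.seed(101)
  areas <- c(A = 1200, B = 340, C = 77)
  sh <- diffusion_shares(c(A = 0.5, B = 0.3, C = 0.2))
  for (k in 1:10) {
    p <- random_params()
    st <- pipeline_state(p, students = stats::runif(p$education_years, 0, 400),
                         retakers = stats::runif(1, 0, 100),
                         gradschool = stats::runif(p$gradschool_years, 0, 50),
                         pharmacists = areas)
    traj <- simulate_supply(st, p, sh, 2000, 30)
    oracle <- oracle_supply(p, sh, st$students, st$retakers, st$gradschool,
                            st$pharmacists, 30)
    for (area in names(areas)) {
      got <- traj$value[traj$area_id == area]
      expect_equal(got, unname(oracle[, area]),
                   tolerance = 1e-9, label = paste("area", area, "rep", k))
    }
  }
})
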