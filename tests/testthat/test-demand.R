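test_that("prescription projection is the age-group dot product", {
  pop <- flat_population(areas = "A", years = 2015, persons = 1000)
  zero <- age_rates(stats::setNames(rep(0, 18), age_groups_5yr()))
  expect_equal(project_prescriptions(pop, zero, "A", 2015), 0)

  one_group <- age_rates(c("30-34" = 10))
  expect_equal(project_prescriptions(pop, one_group, "A", 2015), 10000)

  set.seed(7)
  for (k in 1:20) {
    persons <- stats::runif(18, 0, 5000)
    p <- stats::runif(18, 0, 30)
    pop_k <- population_projection(data.frame(
      area_id = "A", year = 2015L, age_group = age_groups_5yr(),
      persons = persons))
    rates_k <- age_rates(stats::setNames(p, age_groups_5yr()))
    expect_equal(project_prescriptions(pop_k, rates_k, "A", 2015),
                 sum(persons * p))
  }
})

test_that("missing coverage is reported by name", {
  pop <- flat_population(areas = "A", years = 2015)
  r <- age_rates(stats::setNames(rep(1, 18), age_groups_5yr()))
  expect_error(project_prescriptions(pop, r, "B", 2015), "no data")
  expect_error(project_prescriptions(pop, r, "A", 2020), "no data")
  expect_error(project_prescriptions(pop, age_rates(c(weird = 1)), "A", 2015),
               "weird")
})

test_that("demand divides prescriptions by the demand coefficient", {
  pop <- population_projection(data.frame(
    area_id = "A", year = 2015L, age_group = age_groups_5yr(),
    persons = c(80, rep(0, 17))))
  r <- age_rates(stats::setNames(c(1, rep(0, 17)), age_groups_5yr()))
  p8 <- parameter_set(demand_coefficient = 0.8)
  expect_equal(project_demand(pop, r, p8, "A", 2015), 100)
  p1 <- parameter_set(demand_coefficient = 1)
  expect_equal(project_demand(pop, r, p1, "A", 2015),
               project_prescriptions(pop, r, "A", 2015))
  bad <- parameter_set()
  bad$demand_coefficient <- 0
  expect_error(project_demand(pop, r, bad, "A", 2015), "demand_coefficient")
})

test_that("demand is linear in population and additive over areas", {
  set.seed(11)
  persons <- stats::runif(18, 100, 5000)
  rates <- age_rates(stats::setNames(stats::runif(18, 0, 20),
                                     age_groups_5yr()))
  params <- parameter_set()
  mk <- function(scale, area = "A") population_projection(data.frame(
    area_id = area, year = 2015L, age_group = age_groups_5yr(),
    persons = persons * scale))
  d1 <- project_demand(mk(1), rates, params, "A", 2015)
  d3 <- project_demand(mk(3), rates, params, "A", 2015)
  expect_equal(d3, 3 * d1, tolerance = 1e-12)

  two <- population_projection(rbind(as.data.frame(mk(1)),
                                     as.data.frame(mk(2, "B"))))
  dT <- project_demand(two, rates, params, "TOTAL", 2015)
  expect_equal(dT,
               project_demand(two, rates, params, "A", 2015) +
                 project_demand(two, rates, params, "B", 2015),
               tolerance = 1e-9 * dT)
})

test_that("demand trajectories track population and locate the peak year", {
  params <- parameter_set()
  rates <- age_rates(stats::setNames(seq(1, 18), age_groups_5yr()))

  flat <- flat_population(areas = "A", years = 2015:2020)
  tr <- demand_trajectory(flat, rates, params, 2015:2020)
  a <- tr$value[tr$area_id == "A"]
  expect_true(all(abs(a - a[1]) < 1e-9 * a[1]))

  # population halves linearly by the end year; rates fixed => demand halves
  halving <- do.call(rbind, lapply(2015:2020, function(y) {
    f <- 1 - 0.5 * (y - 2015) / 5
    data.frame(area_id = "A", year = y, age_group = age_groups_5yr(),
               persons = 1000 * f)
  }))
  tr2 <- demand_trajectory(population_projection(halving), rates, params,
                           2015:2020)
  v <- tr2$value[tr2$area_id == "A"]
  expect_equal(v[6] / v[1], 0.5, tolerance = 1e-12)
  chg <- attr(tr2, "change_from_baseline")
  expect_equal(chg$change[chg$area_id == "A" & chg$year == 2020], 0.5,
               tolerance = 1e-12)

  # aging but shrinking population: demand rises then falls; the reported
  # peak equals a brute-force year-by-year scan
  years <- 2015:2040
  aging <- do.call(rbind, lapply(years, function(y) {
    t <- y - 2015
    total <- 10000 * (1 - 0.008)^t
    old_share <- min(0.45, 0.25 + 0.012 * t)
    w <- rep((1 - old_share) / 13, 18)
    w[14:18] <- old_share / 5
    data.frame(area_id = "A", year = y, age_group = age_groups_5yr(),
               persons = total * w)
  }))
  pop_aging <- population_projection(aging)
  steep <- age_rates(stats::setNames(c(rep(1, 13), rep(30, 5)),
                                     age_groups_5yr()))
  tr3 <- demand_trajectory(pop_aging, steep, params, years)
  v3 <- tr3$value[tr3$area_id == "A"]
  scan <- vapply(years,
                 function(y) project_demand(pop_aging, steep, params, "A", y),
                 numeric(1))
  peak <- years[which.max(scan)]
  expect_equal(tr3$year[tr3$area_id == "A"][which.max(v3)], peak)
  expect_gt(peak, 2015)
  expect_lt(peak, 2040)
})

test_that("percent population change reproduces the printed projection table", {
  anchors <- hokkaido_population_anchors()
  expect_equal(population_change(anchors, "Total", 2015, 2025), -6.6)
  expect_equal(population_change(anchors, "Sapporo", 2015, 2025), 0.1)
  expect_equal(population_change(anchors, "Total", 2015, 2040), -20.3)
  expect_equal(population_change(anchors, "Minamihiyama", 2015, 2040), -51.7)
  expect_equal(population_change(anchors, "Kitasorachi", 2015, 2025), -18.4)
  expect_equal(population_change(anchors, "Sapporo", 2015, 2015), 0)

  pop <- flat_population(areas = "A", years = 2015:2016)
  expect_equal(population_change(pop, "A", 2015, 2016), 0)
})
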