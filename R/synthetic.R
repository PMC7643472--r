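#' Configuration of the synthetic input generator
#'
#' The generator emulates the external inputs of the projection — official
#' population projections by area/year/age group, age-specific prescription
#' rates, and historical head-count series — with the structure the analysis
#' assumes: per-area totals anchored to the published 2015/2025/2040
#' Hokkaido projections (geometric interpolation in between), an age
#' composition whose 65+ share starts at each area's published aging rate
#' and drifts upward, and prescription rates that rise monotonically with
#' age and are flat from 75 up.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_areas Number of areas; 21 (the default) uses the packaged
#'   Hokkaido areas and anchors, any other count generates synthetic areas
#'   `A01, A02, ...` with rank-size populations.
#' @param start_year,end_year Projection span (calendar years).
#' @param total_population_baseline Prefecture population at `start_year`
#'   (used only for synthetic areas).
#' @param annual_decline Optional constant fractional decline of every area
#'   total per year; `NULL` (default) uses the anchor interpolation for the
#'   Hokkaido areas (or 0.009/year for synthetic areas, the pace implied by
#'   the published 2015-2040 totals).
#' @param aging_drift Annual increase of the 65+ population share
#'   (fraction/year); the published Hokkaido trajectory implies ~0.004.
#' @param rate_young,rate_old Prescriptions per person per year at the young
#'   and old ends of the age curve.
#' @param rate_inflection,rate_slope Age (years) of the logistic inflection
#'   and its scale.
#' @param noise_sd Relative noise applied to the age composition (area
#'   totals and the 65+ share stay exact by construction) and to the
#'   "actual" series of [gen_history()].
#' @param separation_rate Scalar multiplier on generated prescription rates,
#'   converting all-prescription volume to pharmacy-filled volume; 1 keeps
#'   rates unscaled.
#' @param history_years Years of the historical head-count series.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_areas = 21L,
                         start_year = 2015L,
                         end_year = 2040L,
                         total_population_baseline = 5371742,
                         annual_decline = NULL,
                         aging_drift = 0.004,
                         rate_young = 2,
                         rate_old = 8,
                         rate_inflection = 60,
                         rate_slope = 12,
                         noise_sd = 0.02,
                         separation_rate = 1,
                         history_years = 2012:2016) {
  cfg <- list(seed = as.integer(seed), n_areas = as.integer(n_areas),
              start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              total_population_baseline = total_population_baseline,
              annual_decline = annual_decline, aging_drift = aging_drift,
              rate_young = rate_young, rate_old = rate_old,
              rate_inflection = rate_inflection, rate_slope = rate_slope,
              noise_sd = noise_sd, separation_rate = separation_rate,
              history_years = as.integer(history_years))
  if (cfg$end_year < cfg$start_year) {
    stop("'end_year' must not precede 'start_year'", call. = FALSE)
  }
  if (cfg$n_areas < 1) stop("'n_areas' must be >= 1", call. = FALSE)
  if (cfg$total_population_baseline <= 0) {
    stop("'total_population_baseline' must be > 0", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$rate_young < 0 || cfg$rate_old < cfg$rate_young) {
    stop("need 0 <= rate_young <= rate_old", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Japan-like reference age pyramid over the 18 five-year bins (shares).
ref_age_weights <- function() {
  w <- c(4.0, 4.2, 4.4, 4.8, 4.8, 5.1, 5.8, 6.5, 7.7, 7.0, 6.3, 6.0, 6.8,
         7.7, 6.0, 5.0, 3.9, 4.0)
  stats::setNames(w / sum(w), age_groups_5yr())
}

synth_area_frame <- function(cfg) {
  if (cfg$n_areas == 21L) {
    areas <- hokkaido_areas()
    anchors <- hokkaido_population_anchors()
    anchors <- anchors[anchors$area_id != "Total", ]
    df <- dplyr::inner_join(
      as.data.frame(areas)[, c("area_id", "aging_rate")], anchors,
      by = "area_id")
    df$anchored <- TRUE
  } else {
    # rank-size (Zipf) populations, aging rates rising with rank
    k <- seq_len(cfg$n_areas)
    size <- (1 / k) / sum(1 / k) * cfg$total_population_baseline
    df <- data.frame(
      area_id = sprintf("A%02d", k),
      aging_rate = 0.25 + 0.15 * (k - 1) / max(1, cfg$n_areas - 1),
      pop_2015 = size, pop_2025 = NA_real_, pop_2040 = NA_real_,
      anchored = FALSE
    )
  }
  df
}

area_year_totals <- function(cfg, area_row, years) {
  t0 <- cfg$start_year
  if (!is.null(cfg$annual_decline)) {
    return(area_row$pop_2015 * (1 - cfg$annual_decline)^(years - t0))
  }
  if (!isTRUE(area_row$anchored)) {
    return(area_row$pop_2015 * (1 - 0.009)^(years - t0))
  }
  g1 <- (area_row$pop_2025 / area_row$pop_2015)^(1 / 10)
  g2 <- (area_row$pop_2040 / area_row$pop_2025)^(1 / 15)
  vapply(years, function(y) {
    if (y <= 2025) area_row$pop_2015 * g1^(y - 2015)
    else if (y <= 2040) area_row$pop_2025 * g2^(y - 2025)
    else area_row$pop_2040 * g2^(y - 2040)
  }, numeric(1))
}

#' Generate a synthetic population projection
#'
#' Per-area, per-year, per-age-group person counts. Area totals follow the
#' published anchors (or the configured geometric decline) exactly; within a
#' total, the age composition starts from a reference pyramid, is optionally
#' perturbed by seeded multiplicative noise, and is then rescaled so the
#' 65+ share equals the area's aging rate plus `aging_drift` per elapsed
#' year (capped at 0.90). The per-area target totals are attached as
#' attribute `"area_totals"`.
#'
#' @param cfg A [synth_config()].
#' @return A [population_projection()].
#' @export
gen_population <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  years <- seq(cfg$start_year, cfg$end_year)
  bins <- age_groups_5yr()
  old_bins <- bins[seq(14, 18)]  # 65-69 .. 85+
  wref <- ref_age_weights()
  areas <- synth_area_frame(cfg)

  with_preserved_seed(cfg$seed, {
    rows <- vector("list", nrow(areas) * length(years))
    totals <- vector("list", nrow(areas))
    idx <- 0L
    for (i in seq_len(nrow(areas))) {
      ar <- areas[i, ]
      tot <- area_year_totals(cfg, ar, years)
      totals[[i]] <- tibble::tibble(area_id = ar$area_id, year = years,
                                    persons_total = tot)
      for (j in seq_along(years)) {
        w <- wref
        if (cfg$noise_sd > 0) {
          w <- w * pmax(stats::rnorm(length(w), 1, cfg$noise_sd), 0.01)
        }
        w <- w / sum(w)
        theta <- min(0.90, max(0.05,
                               ar$aging_rate + cfg$aging_drift * (years[j] - cfg$start_year)))
        is_old <- names(w) %in% old_bins
        w[is_old] <- w[is_old] * theta / sum(w[is_old])
        w[!is_old] <- w[!is_old] * (1 - theta) / sum(w[!is_old])
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(area_id = ar$area_id, year = years[j],
                                      age_group = bins,
                                      persons = tot[j] * w)
      }
    }
    pop <- population_projection(dplyr::bind_rows(rows))
    attr(pop, "area_totals") <- dplyr::bind_rows(totals)
    pop
  })
}

#' Generate synthetic age-specific prescription rates
#'
#' A logistic curve from `rate_young` to `rate_old` across the age-bin
#' midpoints, flat for all bins from 75 up (prescription behaviour is
#' assumed not to differ among the over-75 groups), scaled by
#' `separation_rate`. Deterministic (no noise: the emulated source is an
#' averaged official statistic).
#'
#' @param cfg A [synth_config()].
#' @return An [age_rates()] vector, monotone non-decreasing in age.
#' @export
gen_rates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  bins <- age_groups_5yr()
  mids <- c(seq(2.5, 82.5, by = 5), 87.5)
  curve <- function(a) {
    cfg$rate_young + (cfg$rate_old - cfg$rate_young) *
      stats::plogis((a - cfg$rate_inflection) / cfg$rate_slope)
  }
  p <- curve(mids)
  flat <- mids >= 75
  p[flat] <- curve(77.5)
  age_rates(stats::setNames(p * cfg$separation_rate, bins))
}

#' Generate a synthetic backtest pair
#'
#' Simulates the supply over the configured history years and produces an
#' "actual" series by perturbing the projected `TOTAL` head-counts with
#' seeded multiplicative noise `N(1, noise_sd)` (clamped at 0.01), so the
#' backtest can be exercised at known ground truth.
#'
#' @param cfg A [synth_config()].
#' @param params A [parameter_set()].
#' @param initial A [pipeline_state()] with per-area stocks; the allocation
#'   shares are taken proportional to the initial stocks.
#' @return A list with `projected` and `actual` `TOTAL` trajectories
#'   (persons).
#' @export
gen_history <- function(cfg, params, initial) {
  stopifnot(inherits(cfg, "synth_config"))
  years <- cfg$history_years
  shares <- diffusion_shares(initial$pharmacists / sum(initial$pharmacists),
                             label = "history")
  traj <- simulate_supply(initial, params, shares, years[1],
                          horizon = length(years) - 1L)
  proj <- traj[traj$area_id == "TOTAL", ]
  projected <- trajectory(as.data.frame(proj), unit = "persons")
  actual <- with_preserved_seed(cfg$seed + 1L, {
    mult <- pmax(stats::rnorm(nrow(projected), 1, cfg$noise_sd), 0.01)
    trajectory(data.frame(area_id = "TOTAL", year = projected$year,
                          value = projected$value * mult),
               unit = "persons")
  })
  list(projected = projected, actual = actual)
}

#' Generate a fully calibrated synthetic input bundle
#'
#' Assembles every input of the end-to-end pipeline — the Hokkaido area
#' table, a warmed-up pipeline state with the baseline per-area stocks, the
#' stock-proportional base diffusion shares, a synthetic population
#' projection and prescription-rate table — and rescales the rates by the
#' unique scalar that makes the start-year `TOTAL` sufficiency ratio equal
#' `target_ratio`. The default 1.19 echoes the published baseline figure;
#' the bundle is synthetic and is labelled as such.
#'
#' @param cfg A [synth_config()].
#' @param target_ratio Requested start-year `TOTAL` sufficiency ratio (> 0).
#' @param params A [parameter_set()].
#' @return A list of class `synthetic_bundle`: `params`, `areas`, `initial`,
#'   `shares`, `population`, `rates`, `target_ratio`, `achieved_ratio`, and
#'   `baseline_prescriptions` (the calibrated start-year `TOTAL` volume).
#' @export
gen_baseline_calibrated <- function(cfg, target_ratio = 1.19,
                                    params = parameter_set()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.finite(target_ratio) || target_ratio <= 0) {
    stop("'target_ratio' must be > 0", call. = FALSE)
  }
  areas <- hokkaido_areas()
  if (cfg$n_areas != 21L) {
    stop("calibrated bundles use the packaged 21-area geography", call. = FALSE)
  }
  initial <- warm_up_pipeline(params)
  initial$pharmacists <- stats::setNames(as.numeric(areas$pharmacists),
                                         areas$area_id)
  shares <- diffusion_shares(
    initial$pharmacists / sum(initial$pharmacists), label = "base")
  pop <- gen_population(cfg)
  rates0 <- gen_rates(cfg)

  capacity <- supply_capacity(sum(initial$pharmacists), params)
  ratio_at <- function(alpha) {
    demand <- project_prescriptions(pop, age_rates(unclass(rates0) * alpha),
                                    "TOTAL", cfg$start_year) /
      params$demand_coefficient
    capacity / demand
  }
  # ratio is proportional to 1/alpha: bracket the root and solve
  r1 <- ratio_at(1)
  guess <- r1 / target_ratio
  alpha <- stats::uniroot(function(a) ratio_at(a) - target_ratio,
                          lower = guess / 10, upper = guess * 10,
                          tol = 1e-12)$root
  rates <- age_rates(stats::setNames(unclass(rates0) * alpha, names(rates0)))

  bundle <- list(
    params = params, areas = areas, initial = initial, shares = shares,
    population = pop, rates = rates, target_ratio = target_ratio,
    achieved_ratio = ratio_at(alpha),
    baseline_prescriptions = project_prescriptions(pop, rates, "TOTAL",
                                                   cfg$start_year)
  )
  class(bundle) <- "synthetic_bundle"
  bundle
}
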