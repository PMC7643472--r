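scale_population <- function(pop, annual_factor, start_year) {
  df <- as.data.frame(pop)
  df$persons <- df$persons * annual_factor^(df$year - start_year)
  out <- population_projection(df)
  out
}

default_sweeps <- function(bundle, cfg) {
  lowpop <- scale_population(bundle$population, 1 - 0.003, cfg$start_year)
  highpop <- scale_population(bundle$population, 1 + 0.003, cfg$start_year)
  list(
    sweep_spec("prescriptions_per_pharmacist_per_day", 15, 17.6, 25),
    sweep_spec("pass_rate", 0.638, 0.738, 0.838),
    sweep_spec("enrollments", 360, 399.8, 440),
    sweep_spec("attrition_rate", 0.002, 0.007, 0.012),
    sweep_spec("prescriptions_per_person_multiplier", 0.9, 1.0, 1.1),
    sweep_spec("population_variant", lowpop, bundle$population, highpop)
  )
}

write_report_csv <- function(rep, path) {
  df <- data.frame(area_id = rep$area_id, year = rep$year,
                   ratio = fmt_num(rep$ratio), flag = rep$flag,
                   stringsAsFactors = FALSE)
  write_csv_checked(df, path)
}

#' Run the full projection workflow end-to-end
#'
#' Generates (or loads) every input, runs the supply simulation, the demand
#' projection, the sufficiency evaluation, the historical backtest, the
#' sensitivity sweeps and the diffusion scenarios, and writes all results as
#' delimited text plus a reproducibility manifest. With a fixed seed the
#' output directory is byte-identical across runs (excluding the manifest
#' timestamp).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all synthetic generation.
#' @param target_ratio Start-year `TOTAL` sufficiency ratio the synthetic
#'   bundle is calibrated to (the packaged documentation fixture uses 1.19).
#' @param config Optional path to a parameter config file
#'   (see [load_parameters()]); `NULL` uses the base-case defaults.
#' @param cfg A [synth_config()]; defaults to `synth_config(seed)`.
#' @return `out_dir`, invisibly. Files written: `areas.csv`,
#'   `population.csv`, `rates.csv`, `shares.csv`, `supply.csv`,
#'   `flow_log.csv`, `demand.csv`, `sufficiency.csv`, `history.csv`,
#'   `validation.json`, `sweeps.csv`, `scenarios.csv`, `manifest.json`.
#' @export
run_full <- function(out_dir, seed = 1L, target_ratio = 1.19, config = NULL,
                     cfg = synth_config(seed = seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(file, writer) {
    path <- file.path(out_dir, file)
    writer(path)
    written <<- c(written, path)
    path
  }
  on_error <- function(e, stage) {
    unlink(written)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_error(e, name))
  }

  params <- stage("load_parameters",
                  if (is.null(config)) parameter_set() else
                    load_parameters(config))
  bundle <- stage("synthetic_inputs",
                  gen_baseline_calibrated(cfg, target_ratio = target_ratio,
                                          params = params))
  stage("write_inputs", {
    emit("areas.csv", function(p) {
      full <- rbind(attr(bundle$areas, "total"), as.data.frame(bundle$areas))
      write_csv_checked(full, p)
    })
    emit("population.csv", function(p) write_population(bundle$population, p))
    emit("rates.csv", function(p) write_rates(bundle$rates, p))
    emit("shares.csv", function(p) write_shares(bundle$shares, p))
  })

  years <- seq(cfg$start_year, cfg$end_year)
  supply <- stage("supply", simulate_supply(bundle$initial, params,
                                            bundle$shares, cfg$start_year,
                                            length(years) - 1L))
  stage("write_supply", {
    emit("supply.csv", function(p) write_trajectory(supply, p))
    emit("flow_log.csv", function(p) {
      df <- as.data.frame(flow_log(supply))
      df[-1] <- lapply(df[-1], fmt_num)
      write_csv_checked(df, p)
    })
  })

  demand <- stage("demand", demand_trajectory(bundle$population, bundle$rates,
                                              params, years))
  stage("write_demand", emit("demand.csv",
                             function(p) write_trajectory(demand, p)))

  report <- stage("sufficiency", build_report(supply, demand, params))
  stage("write_sufficiency", emit("sufficiency.csv",
                                  function(p) write_report_csv(report, p)))

  hist <- stage("backtest_inputs", gen_history(cfg, params, bundle$initial))
  validation <- stage("backtest", rmse_backtest(hist$projected, hist$actual))
  stage("write_backtest", {
    emit("history.csv", function(p) write_history(hist$actual, p))
    emit("validation.json", function(p) {
      jsonlite::write_json(
        list(rmse = validation$rmse, n = validation$n,
             per_year_relative_error =
               as.list(validation$per_year_relative_error),
             passed = validation$passed, threshold = validation$threshold),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  })

  sweeps <- stage("sweeps", dplyr::bind_rows(
    lapply(default_sweeps(bundle, cfg), run_sweep, baseline = bundle)))
  stage("write_sweeps", emit("sweeps.csv", function(p) {
    df <- as.data.frame(sweeps)
    df$value <- fmt_num(df$value)
    df$ratio <- fmt_num(df$ratio)
    write_csv_checked(df, p)
  }))

  scen <- stage("scenarios", run_scenarios(
    list(scenario_spec("base", hokkaido_shares("base")),
         scenario_spec("previous_trend", hokkaido_shares("previous_trend")),
         scenario_spec("recent_trend", hokkaido_shares("recent_trend"))),
    bundle))
  stage("write_scenarios", emit("scenarios.csv", function(p) {
    df <- as.data.frame(scen)
    df$ratio <- fmt_num(df$ratio)
    write_csv_checked(df, p)
  }))

  stage("manifest", {
    inputs <- file.path(out_dir, c("areas.csv", "population.csv", "rates.csv",
                                   "shares.csv"))
    manifest <- list(
      package = "pharmflow",
      version = as.character(utils::packageVersion("pharmflow")),
      subcommand = "run",
      seed = cfg$seed,
      target_ratio = target_ratio,
      config = if (is.null(config)) NA else
        unname(tools::md5sum(config)),
      input_hashes = as.list(tools::md5sum(inputs)),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    names(manifest$input_hashes) <- basename(names(manifest$input_hashes))
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  })

  invisible(out_dir)
}
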