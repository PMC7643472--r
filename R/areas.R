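#' Read an area profile table
#'
#' Area tables describe the secondary medical areas of a prefecture: one row
#' per area with its baseline pharmacist head-count, population, aging rate
#' (share of population aged 65+) and land area. A `Total` row, if present,
#' is split off into the `"total"` attribute and never summed into the areas.
#'
#' @param path CSV with header
#'   `area_id,name,pharmacists,population,aging_rate,land_area_km2`.
#' @return A tibble of per-area profiles (class `area_table`), with the
#'   prefecture-wide `Total` row (if any) as attribute `"total"`.
#' @export
#' @examples
#' areas <- hokkaido_areas()
#' areas[areas$area_id == "Sapporo", ]
#' attr(areas, "total")
load_area_table <- function(path) {
  expected <- c("area_id", "name", "pharmacists", "population",
                "aging_rate", "land_area_km2")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), expected)) {
    stop(sprintf("area table '%s' must have columns %s (got %s)",
                 path, paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  is_total <- df$area_id == "Total"
  total <- df[is_total, , drop = FALSE]
  df <- df[!is_total, , drop = FALSE]
  if (anyDuplicated(df$area_id)) {
    dup <- unique(df$area_id[duplicated(df$area_id)])
    stop(sprintf("duplicate area_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$pharmacists < 0)) stop("negative pharmacist counts", call. = FALSE)
  if (any(df$population <= 0)) stop("populations must be > 0", call. = FALSE)
  if (any(df$aging_rate < 0 | df$aging_rate > 1)) {
    stop("aging_rate must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "total") <- if (nrow(total)) tibble::as_tibble(total) else NULL
  class(out) <- c("area_table", class(out))
  out
}

pf_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pharmflow")
  if (path == "") {
    # during development (pkgload) inst/ may not be installed yet
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Packaged Hokkaido area fixtures
#'
#' `hokkaido_areas()` returns the 21 secondary medical areas of Hokkaido with
#' their 2015 populations, 2015 aging rates, 2014 pharmacist head-counts and
#' land areas; the prefecture Total is attached as attribute `"total"`.
#' `hokkaido_population_anchors()` returns the official projected populations
#' (2015, 2025, 2040) per area, used to anchor the synthetic population
#' generator.
#'
#' @return `hokkaido_areas()`: an `area_table`;
#'   `hokkaido_population_anchors()`: a tibble with columns
#'   `area_id, pop_2015, pop_2025, pop_2040`.
#' @export
hokkaido_areas <- function() {
  load_area_table(pf_extdata("hokkaido_areas.csv"))
}

#' @rdname hokkaido_areas
#' @export
hokkaido_population_anchors <- function() {
  df <- utils::read.csv(pf_extdata("hokkaido_population_anchors.csv"),
                        stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Diffusion shares of newly licensed pharmacists
#'
#' The fraction of each year's newly licensed pharmacy pharmacists allocated
#' to each medical area. Shares may be negative (trend-derived share vectors
#' show net outflow for some areas) but must sum to 1: sums within 0.01 of 1
#' are silently renormalized (published tables are rounded to 0.1%),
#' deviations in (0.01, 0.05] renormalize with a warning, and larger
#' deviations are an error.
#'
#' @param shares Named numeric vector (names are area ids), or a data frame
#'   with columns `area_id` and `share`.
#' @param label Scenario name.
#' @return An object of class `diffusion_shares`: a named numeric vector
#'   summing to 1 (within 1e-6) with a `"label"` attribute.
#' @export
#' @examples
#' diffusion_shares(c(A = 0.6, B = 0.4), label = "toy")
diffusion_shares <- function(shares, label = "custom") {
  if (is.data.frame(shares)) {
    stopifnot(all(c("area_id", "share") %in% names(shares)))
    shares <- stats::setNames(as.numeric(shares$share), shares$area_id)
  }
  if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
    stop("shares must be named by area_id", call. = FALSE)
  }
  if (anyDuplicated(names(shares))) {
    stop("duplicate area ids in shares", call. = FALSE)
  }
  s <- sum(shares)
  dev <- abs(s - 1)
  if (dev > 0.05) {
    stop(sprintf("shares sum to %.4f; deviation from 1 exceeds 0.05", s),
         call. = FALSE)
  }
  if (dev > 0.01) {
    warning(sprintf("shares sum to %.4f; renormalizing", s), call. = FALSE)
  }
  if (dev > 1e-12) shares <- shares / s
  structure(shares, label = label, class = "diffusion_shares")
}

#' Packaged diffusion-share scenarios for Hokkaido
#'
#' Three share vectors over the 21 medical areas: `"base"` (the current
#' distribution of pharmacists), `"previous_trend"` (net diffusion trend of
#' newly licensed pharmacists in 2006-2012) and `"recent_trend"` (the
#' 2012-2016/2018 trend, which concentrates licensees in Sapporo and shows
#' net outflow in several rural areas).
#'
#' @param scenario One of `"base"`, `"previous_trend"`, `"recent_trend"`.
#' @return A `diffusion_shares` object.
#' @export
hokkaido_shares <- function(scenario = c("base", "previous_trend",
                                         "recent_trend")) {
  scenario <- match.arg(scenario)
  path <- pf_extdata(paste0("shares_", scenario, ".csv"))
  diffusion_shares(read_shares(path), label = scenario)
}
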