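phase_breaks <- function() {
  list(initial_2016_20 = 2016:2020, mid_2021_25 = 2021:2025,
       end_2026_30 = 2026:2030)
}

#' Aggregate annual costs into scale-up phases
#'
#' The 15-year horizon partitions into the initial (2016-20), mid-term
#' (2021-25) and end-term (2026-30) scale-up phases; headline resource needs
#' are reported as the mean annual need during the mature end-term phase.
#'
#' @param cost_lines Cost-line tibble (or a `year`/`amount` tibble).
#' @return Tibble (phase, total_cost, mean_annual_cost); the phase totals
#'   sum to the 15-year total.
#' @export
phase_aggregate <- function(cost_lines) {
  by_year <- cost_by_year(cost_lines)
  purrr::imap_dfr(phase_breaks(), function(yrs, ph) {
    tot <- sum(by_year$amount[by_year$year %in% yrs])
    tibble::tibble(phase = ph, total_cost = tot, mean_annual_cost = tot / 5)
  })
}

#' Per-person cost, rounded half-up to the nearest dollar
#'
#' @param cost Total cost, US$.
#' @param population Persons (> 0).
#' @return Integer dollars; exact halves round up (58.5 becomes 59).
#' @export
#' @examples
#' per_person(371e9, 6286e6)  # 59
per_person <- function(cost, population) {
  if (any(!is.finite(population)) || any(population <= 0))
    stop("population must be > 0", call. = FALSE)
  floor(cost / population + 0.5)
}

#' Population-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights (populations) with positive sum.
#' @return `sum(w v) / sum(w)`, guaranteed inside `[min(v), max(v)]`.
#' @export
weighted_mean_pop <- function(values, weights) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be >= 0 with positive sum", call. = FALSE)
  sum(values * weights) / sum(weights)
}

run_population <- function(run, years = NULL) {
  p <- apply(run$projection$population, 3, sum)
  if (is.null(years)) p else p[as.character(years)]
}

#' Group summary of resource needs
#'
#' One row per group (typology, income group, or all countries): country
#' count, mean end-term population, phase cost summaries, the
#' population-weighted mean incremental cost per person in 2030 with its
#' across-country range, and total cost per person in 2030 (baseline
#' expenditure plus incremental, on both total and government-expenditure
#' baselines).
#'
#' @param runs List of `country_run` objects.
#' @param grouping `"typology"`, `"income_group"` or `"all"`.
#' @return Summary tibble, full precision (round only for display).
#' @export
group_cost_summary <- function(runs, grouping = c("all", "typology", "income_group")) {
  grouping <- match.arg(grouping)
  per_country <- purrr::map_dfr(runs, function(r) {
    by_year <- cost_by_year(r$incremental)
    pop30 <- run_population(r, 2030)
    end_pop <- mean(run_population(r, 2026:2030))
    ph <- phase_aggregate(r$incremental)
    the0 <- r$financing$the_pc[1] - r$financing$available_incremental_pc[1]
    tibble::tibble(
      country_id = r$country_id,
      group = switch(grouping, all = "all_countries",
                     typology = r$typology, income_group = r$income_group),
      total_cost = sum(by_year$amount),
      initial = ph$mean_annual_cost[1], mid = ph$mean_annual_cost[2],
      end = ph$mean_annual_cost[3],
      cost_2030 = by_year$amount[by_year$year == 2030],
      pop_2030 = pop30, end_pop = end_pop,
      pp_2030 = by_year$amount[by_year$year == 2030] / pop30,
      the_pp_2030 = the0 + by_year$amount[by_year$year == 2030] / pop30)
  })
  per_country %>% dplyr::group_by(group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_population_end_term = sum(.data$end_pop),
      total_cost_2016_30 = sum(.data$total_cost),
      mean_annual_initial = sum(.data$initial),
      mean_annual_mid = sum(.data$mid),
      mean_annual_end = sum(.data$end),
      per_person_2030 = weighted_mean_pop(.data$pp_2030, .data$pop_2030),
      per_person_min = min(.data$pp_2030),
      per_person_max = max(.data$pp_2030),
      per_person_end_term = sum(.data$end) / sum(.data$end_pop),
      total_cost_pp_the = weighted_mean_pop(.data$the_pp_2030, .data$pop_2030),
      .groups = "drop")
}

#' Deaths-averted summary by cause
#'
#' @param runs List of `country_run` objects.
#' @return Tibble (cause, averted): 2016-30 totals over all countries.
#' @export
deaths_averted_summary <- function(runs) {
  purrr::map_dfr(runs, function(r) r$impact$deaths_averted) %>%
    dplyr::group_by(cause) %>%
    dplyr::summarise(averted = sum(averted), .groups = "drop")
}

#' Financing-gap inputs per country
#'
#' @param runs List of `country_run` objects.
#' @param grouping `"typology"` or `"income_group"`.
#' @return Tibble suitable for [gap_summary()].
#' @export
gap_inputs <- function(runs, grouping = c("typology", "income_group")) {
  grouping <- match.arg(grouping)
  purrr::map_dfr(runs, function(r) {
    tibble::tibble(country_id = r$country_id,
                   group = if (grouping == "typology") r$typology else r$income_group,
                   year = r$gap$year, gap = r$gap$gap,
                   population = unname(run_population(r)))
  })
}

#' Export run results as deterministic CSV tables
#'
#' Writes group-level resource-need tables (by typology and income group,
#' plus an all-countries row), the financing-gap summary, deaths averted by
#' cause, the cost decomposition by component and platform, and a run
#' manifest (seed, configuration hash, package and R versions).  Output is
#' byte-deterministic for a fixed run.
#'
#' @param runs List of `country_run` objects.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(runs, out_dir, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  costs <- dplyr::bind_rows(group_cost_summary(runs, "typology"),
                            group_cost_summary(runs, "income_group"),
                            group_cost_summary(runs, "all"))
  gaps <- gap_summary(gap_inputs(runs, "typology"))
  da <- deaths_averted_summary(runs)
  decomp <- purrr::map_dfr(runs, function(r) r$incremental) %>%
    dplyr::group_by(component, platform) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  paths <- c(
    costs = file.path(out_dir, "resource_needs_by_group.csv"),
    gaps = file.path(out_dir, "financing_gap_by_group.csv"),
    deaths = file.path(out_dir, "deaths_averted_by_cause.csv"),
    decomp = file.path(out_dir, "cost_decomposition.csv"),
    manifest = file.path(out_dir, "run_manifest.json"))
  readr::write_csv(costs, paths[["costs"]])
  readr::write_csv(gaps, paths[["gaps"]])
  readr::write_csv(da, paths[["deaths"]])
  readr::write_csv(decomp, paths[["decomp"]])
  manifest <- list(seed = seed,
                   config_hash = rlang::hash(list(costs, gaps, da, decomp)),
                   n_countries = length(runs),
                   package_version = as.character(utils::packageVersion("uhcproj")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
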