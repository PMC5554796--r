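#' Run the full projection for one country
#'
#' Builds scenario and flatline coverage paths, projects populations under
#' both, costs both streams bottom-up, differences them into incremental
#' costs (optionally scaled by an efficiency factor), computes the health
#' impact (deaths averted, life-expectancy gains against the 2015 baseline
#' and the flatline counterfactual, healthy life-years), and projects the
#' financing space and gap.
#'
#' @param profile Validated [country_profile()].
#' @param catalogue Intervention catalogue.
#' @param bm A [benchmarks()] object (defaults to the income-group default).
#' @param scenario A [scenario_spec()] (`"progress"` or `"ambitious"`).
#' @param fscenario A [financing_scenario()].
#' @param efficiency Positive cost-efficiency factor (1 = as modelled).
#' @param conditions Morbidity conditions for healthy-life-year accounting.
#' @param price_multiplier Country price-level adjustment.
#' @return List of class `country_run` with elements `country_id`,
#'   `scenario`, `coverage`, `coverage_flatline`, `projection`,
#'   `projection_flatline`, `cost_lines` (gross), `cost_lines_flatline`,
#'   `incremental` (cost lines), `impact` (deaths averted, life tables,
#'   le gains, hly), `financing`, `gap`.
#' @export
run_country <- function(profile, catalogue, bm = NULL,
                        scenario = scenario_spec("ambitious"),
                        fscenario = financing_scenario("optimistic"),
                        efficiency = 1,
                        conditions = default_conditions(),
                        price_multiplier = 1) {
  stopifnot(length(validate_profile(profile)) == 0)
  if (is.null(bm)) bm <- benchmarks(profile$income_group)
  flat_spec <- scenario_spec("flatline",
                             target_attainment_year = scenario$target_attainment_year)
  cov_s <- build_coverage_paths(profile, catalogue, scenario)
  cov_f <- build_coverage_paths(profile, catalogue, flat_spec)
  proj_s <- project_population(profile, catalogue, cov_s)
  proj_f <- project_population(profile, catalogue, cov_f)

  lines_s <- country_cost_lines(profile, catalogue, bm, cov_s, proj_s,
                                scenario, price_multiplier)
  lines_f <- country_cost_lines(profile, catalogue, bm, cov_f, proj_f,
                                flat_spec, price_multiplier)
  incr <- apply_efficiency(incremental_costs(lines_s, lines_f), efficiency)

  da <- deaths_averted(proj_s, proj_f)
  lt_s <- life_table(projection_rates(proj_s, 2030))
  lt_f <- life_table(projection_rates(proj_f, 2030))
  lt_b <- life_table(baseline_rates(profile))
  gains <- le_gains(lt_s, lt_f, lt_b)
  hly <- healthy_life_years(proj_s, proj_f, cov_s, cov_f, catalogue, conditions)

  pop_s <- apply(proj_s$population, 3, sum)
  fin <- project_financing(profile, fscenario, pop_s)
  gap <- financing_gap(cost_by_year(incr), fin)

  structure(list(
    country_id = profile$country_id, scenario = scenario$name,
    income_group = profile$income_group, typology = profile$typology,
    coverage = cov_s, coverage_flatline = cov_f,
    projection = proj_s, projection_flatline = proj_f,
    cost_lines = lines_s, cost_lines_flatline = lines_f,
    incremental = incr,
    impact = list(deaths_averted = da, life_table_scenario = lt_s,
                  life_table_flatline = lt_f, life_table_2015 = lt_b,
                  le_gains = gains, hly = hly),
    financing = fin, gap = gap), class = "country_run")
}

#' Run the projection for an ensemble of countries
#'
#' @param profiles List of validated profiles.
#' @param catalogue Intervention catalogue.
#' @param ... Passed to [run_country()].
#' @return List of `country_run` objects, named by country id.
#' @export
run_ensemble <- function(profiles, catalogue, ...) {
  runs <- purrr::map(profiles, run_country, catalogue = catalogue, ...)
  names(runs) <- purrr::map_chr(runs, "country_id")
  runs
}
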