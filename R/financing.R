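#' Financing-space scenario
#'
#' Describes how the fiscal envelope for health evolves: government revenue
#' as a share of GDP, the health share of government spending, and the
#' elasticity of non-government health spending to GDP.  The optimistic
#' default converges the health allocation linearly towards a normative
#' ceiling (15% of government spending) by 2030; the moderate default holds
#' baseline shares, so fiscal space grows only with the economy.  Share
#' paths are expressed relative to each country's baseline shares.
#'
#' @param name `"optimistic"` or `"moderate"`.
#' @param health_allocation_ceiling Normative ceiling on the health share of
#'   government spending (optimistic scenario).
#' @param revenue_uplift Additive increase in the revenue share of GDP
#'   reached by 2030 (optimistic scenario).
#' @param gdp_elasticity Elasticity of non-government health spending to GDP
#'   per person.
#' @return A list of class `financing_scenario`.
#' @export
financing_scenario <- function(name = c("optimistic", "moderate"),
                               health_allocation_ceiling = 0.15,
                               revenue_uplift = 0.02,
                               gdp_elasticity = 1.0) {
  name <- match.arg(name)
  stopifnot(gdp_elasticity > 0)
  structure(list(name = name,
                 health_allocation_ceiling = health_allocation_ceiling,
                 revenue_uplift = if (name == "optimistic") revenue_uplift else 0,
                 gdp_elasticity = gdp_elasticity),
            class = "financing_scenario")
}

#' Project available health financing
#'
#' GDP per person compounds at the profile's annual growth rates.
#' Government health expenditure scales with GDP and the scenario's share
#' paths (anchored as ratios to the baseline shares, so the 2015 level is
#' reproduced exactly at baseline shares); the non-government component
#' scales with GDP per person raised to the scenario elasticity.  Available
#' incremental financing is total health expenditure per person above the
#' 2015 level, times the year's population: a country with zero growth and
#' unchanged shares has zero incremental space.
#'
#' @param profile A validated [country_profile()].
#' @param fscenario A [financing_scenario()].
#' @param population Named vector of projected population per year (from the
#'   scenario's `population_projection`).
#' @return Tibble (year, gdp_pc, gghe_pc, the_pc, available_incremental_pc,
#'   available_incremental), US$ 2014.
#' @export
project_financing <- function(profile, fscenario, population) {
  years <- projection_years()
  ny <- length(years)
  gdp_pc <- profile$gdp_per_capita_2015 * cumprod(1 + profile$gdp_growth)
  u <- (years - 2015) / (2030 - 2015)
  rev0 <- profile$govt_revenue_share
  alloc0 <- profile$health_share_of_govt
  rev_path <- pmin(1, rev0 + u * fscenario$revenue_uplift)
  alloc_path <- if (fscenario$name == "optimistic")
    pmax(alloc0, alloc0 + u * (fscenario$health_allocation_ceiling - alloc0))
  else rep(alloc0, ny)
  gghe_pc <- profile$gghe_per_capita_2014 *
    (gdp_pc / profile$gdp_per_capita_2015) *
    (rev_path / rev0) * (alloc_path / alloc0)
  nongov0 <- profile$the_per_capita_2014 - profile$gghe_per_capita_2014
  nongov_pc <- nongov0 * (gdp_pc / profile$gdp_per_capita_2015)^fscenario$gdp_elasticity
  the_pc <- gghe_pc + nongov_pc
  inc_pc <- the_pc - profile$the_per_capita_2014
  tibble::tibble(year = years, gdp_pc = gdp_pc, gghe_pc = gghe_pc,
                 the_pc = the_pc, available_incremental_pc = inc_pc,
                 available_incremental = inc_pc * unname(population))
}

#' Financing gap by year
#'
#' @param incremental_cost Tibble (year, amount) of incremental costs.
#' @param fin_projection Tibble from [project_financing()].
#' @return Tibble (year, gap): positive part of incremental cost minus
#'   available incremental financing.
#' @export
financing_gap <- function(incremental_cost, fin_projection) {
  d <- dplyr::left_join(fin_projection["year"], incremental_cost, by = "year")
  d$amount[is.na(d$amount)] <- 0
  tibble::tibble(year = d$year,
                 gap = pmax(0, d$amount - fin_projection$available_incremental))
}

#' Group summary of financing gaps
#'
#' A country is counted iff its gap is positive in at least one year of the
#' period; its contribution is the mean gap and mean population over its own
#' gap years only, and group totals sum country contributions.
#'
#' @param country_gaps Tibble with columns `country_id`, `group`, `year`,
#'   `gap` (US$), `population` (persons).
#' @param period Years considered (default the end-term phase 2026-2030).
#' @return Tibble (group, n_countries_with_gap,
#'   mean_population_during_gap_years in millions, mean_annual_gap in US$
#'   billions); groups with no gap get n = 0 and zeros.
#' @export
gap_summary <- function(country_gaps, period = 2026:2030) {
  d <- country_gaps %>% dplyr::filter(year %in% period)
  per_country <- d %>% dplyr::group_by(group, country_id) %>%
    dplyr::summarise(
      has_gap = any(.data$gap > 0),
      mean_gap = if (any(.data$gap > 0)) mean(.data$gap[.data$gap > 0]) else 0,
      mean_pop = if (any(.data$gap > 0)) mean(.data$population[.data$gap > 0]) else 0,
      .groups = "drop")
  per_country %>% dplyr::group_by(group) %>%
    dplyr::summarise(
      n_countries_with_gap = sum(.data$has_gap),
      mean_population_during_gap_years = sum(.data$mean_pop[.data$has_gap]) / 1e6,
      mean_annual_gap = sum(.data$mean_gap[.data$has_gap]) / 1e9,
      .groups = "drop")
}
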