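cost_components <- function() {
  c("drugs_supplies", "program_costs", "workforce", "infrastructure",
    "supply_chain", "governance_his_other")
}

cost_line <- function(country_id, year, component, platform = "none", amount) {
  tibble::tibble(country_id = country_id, year = as.integer(year),
                 component = component, platform = platform, amount = amount)
}

# expand a pin rule into per-cell fractions over the 19 x 2 grid
pin_cells <- function(pin_rule) {
  m <- matrix(0, 19, 2, dimnames = list(age_bands()$band, sexes()))
  for (j in seq_len(nrow(pin_rule))) {
    sx <- if (pin_rule$sex[j] == "both") sexes() else pin_rule$sex[j]
    m[pin_rule$band[j], sx] <- m[pin_rule$band[j], sx] + pin_rule$fraction[j]
  }
  pmin(m, 1)
}

#' Population in need of an intervention in a given year
#'
#' Sums, over age/sex cells, the scenario's own projected population times
#' the intervention's fraction-in-need.  Because the projection already
#' reflects the scenario's mortality reductions, need is dynamic: deaths
#' averted in earlier years enlarge later populations in need.
#'
#' @param profile A [country_profile()] (used for its identifier).
#' @param interv One catalogue row.
#' @param year Calendar year covered by the projection.
#' @param projection A `population_projection` for the same scenario.
#' @return Persons in need (count, >= 0).
#' @export
population_in_need <- function(profile, interv, year, projection) {
  t <- match(year, projection$years)
  if (is.na(t)) stop("year outside projection range", call. = FALSE)
  sum(pin_cells(interv$pin_rule[[1]]) * projection$population[, , t])
}

#' Direct cost of one intervention-year
#'
#' Ingredients-based: population in need x coverage x units per case x unit
#' price x country price multiplier x health-sector share.  Programme
#' support (administration, supervision, campaigns) is added as a
#' `program_costs` line proportional to the direct cost.
#'
#' @inheritParams population_in_need
#' @param coverage Coverage fraction in `[0,1]`.
#' @param price_multiplier Country price-level adjustment.
#' @return Tibble of cost lines (US$ 2014).
#' @export
intervention_cost <- function(profile, interv, year, coverage, projection,
                              price_multiplier = 1) {
  if (!is.finite(coverage) || coverage < 0 || coverage > 1)
    stop("coverage must lie in [0,1]", call. = FALSE)
  if (interv$units_per_case < 0 || interv$unit_price < 0 || price_multiplier < 0)
    stop("costing inputs must be >= 0", call. = FALSE)
  pin <- population_in_need(profile, interv, year, projection)
  direct <- pin * coverage * interv$units_per_case * interv$unit_price *
    price_multiplier * interv$health_sector_share
  dplyr::bind_rows(
    cost_line(profile$country_id, year, "drugs_supplies", interv$platform, direct),
    cost_line(profile$country_id, year, "program_costs", interv$platform,
              direct * interv$program_cost_share))
}

# vectorised service costing over the whole catalogue and horizon
service_costs <- function(profile, catalogue, coverage, projection,
                          price_multiplier = 1) {
  years <- projection$years; ny <- length(years)
  P <- t(vapply(catalogue$pin_rule, function(pr) as.vector(pin_cells(pr)),
                numeric(38)))
  popm <- matrix(projection$population, nrow = 38, ncol = ny)
  pin <- P %*% popm                                   # interventions x years
  scale <- catalogue$units_per_case * catalogue$unit_price *
    price_multiplier * catalogue$health_sector_share
  direct <- pin * coverage[catalogue$intervention_id, , drop = FALSE] * scale
  progc <- direct * catalogue$program_cost_share
  mk <- function(m, comp) {
    agg <- rowsum(m, catalogue$platform)
    d <- as.data.frame.table(as.matrix(agg), stringsAsFactors = FALSE)
    cost_line(profile$country_id, years[match(d$Var2, colnames(agg))],
              comp, d$Var1, d$Freq)
  }
  dplyr::bind_rows(mk(direct, "drugs_supplies"), mk(progc, "program_costs"))
}

#' Workforce scale-up plan and costs
#'
#' Density targets (per 1000 population) are approached by closing the gap
#' between current and target density linearly from 2015 to the scenario's
#' attainment year, scaled by the scenario's benchmark ambition; required
#' headcount applies the effective density to the scenario's own projected
#' population.  Headcount never decreases.  Annual cost is salaries for the
#' full headcount plus one-off training costs for new hires.
#'
#' @param profile A [country_profile()].
#' @param bm A [benchmarks()] object.
#' @param projection The scenario's `population_projection`.
#' @param scenario A [scenario_spec()].
#' @return List: `staffing` tibble (cadre, year, headcount, hires) and
#'   `lines` of `workforce` cost.
#' @export
workforce_plan <- function(profile, bm, projection, scenario) {
  years <- projection$years
  pop_t <- apply(projection$population, 3, sum)
  pop15 <- sum(profile$population_base)
  attain <- scenario$target_attainment_year
  frac <- pmin(1, (years - 2015) / (attain - 2015))
  amb <- scenario$benchmark_ambition
  staffing <- purrr::map_dfr(names(bm$workforce_density_target), function(cd) {
    cur_d <- profile$workforce_density_base[[cd]]
    eff_d <- cur_d + amb * max(0, bm$workforce_density_target[[cd]] - cur_d)
    cur_n <- cur_d * pop15 / 1000
    req_n <- eff_d * pop_t[match(min(attain, max(years)), years)] / 1000
    path <- cummax(cur_n + frac * (req_n - cur_n))
    hires <- pmax(0, diff(c(cur_n, path)))
    tibble::tibble(cadre = cd, year = years, headcount = path, hires = hires)
  })
  cost <- staffing %>%
    dplyr::mutate(amount = .data$headcount * bm$salary[.data$cadre] +
                    .data$hires * bm$training_cost[.data$cadre]) %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  list(staffing = staffing,
       lines = cost_line(profile$country_id, cost$year, "workforce",
                         "none", cost$amount))
}

#' Infrastructure build plan and costs
#'
#' Facilities to build close the gap between the current stock and the
#' target density applied to the 2030 population (scaled by scenario
#' ambition).  Construction is phased over 2016-2029 with annual volumes
#' proportional to elapsed years, so annual capital spending is maximal in
#' 2029 and the programme completes by end-2029 (service access is maximised
#' in 2030).  Capital is charged in the construction year; operating costs
#' accrue on the cumulative built stock from the following year.
#'
#' @inheritParams workforce_plan
#' @return List: `schedule` tibble (level, year, built) and `lines` of
#'   `infrastructure` cost.
#' @export
infrastructure_plan <- function(profile, bm, projection, scenario) {
  years <- projection$years
  pop15 <- sum(profile$population_base)
  pop30 <- apply(projection$population, 3, sum)[match(2030, years)]
  amb <- scenario$benchmark_ambition
  build_years <- years[years <= 2029]
  w <- (build_years - 2015) / sum(build_years - 2015)
  schedule <- purrr::map_dfr(names(bm$facility_density_target), function(lv) {
    cur_d <- profile$facility_density_base[[lv]]
    eff_d <- cur_d + amb * max(0, bm$facility_density_target[[lv]] - cur_d)
    stock <- cur_d * pop15 / 10000
    gap <- max(0, eff_d * pop30 / 10000 - stock)
    tibble::tibble(level = lv, year = build_years, built = gap * w)
  })
  capex <- schedule %>%
    dplyr::mutate(amount = .data$built * bm$facility_capex[.data$level]) %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  capex_full <- setNames(numeric(length(years)), years)
  capex_full[as.character(capex$year)] <- capex$amount
  opex <- bm$facility_opex_share * head(cumsum(c(0, capex_full)), length(years))
  list(schedule = schedule,
       lines = cost_line(profile$country_id, years, "infrastructure", "none",
                         unname(capex_full) + opex))
}

#' System-wide overhead costs
#'
#' Governance, health information, supply chain, emergency risk management
#' and health-financing administration, each either a fixed US$ per person
#' (scaling with population only) or a percentage of that year's service
#' costs.
#'
#' @param profile A [country_profile()].
#' @param bm A [benchmarks()] object (its `overhead_rules`).
#' @param service_cost_by_year Named vector of service costs per year.
#' @param projection The scenario's `population_projection`.
#' @return Tibble of cost lines, one per component-year.
#' @export
systems_overhead_costs <- function(profile, bm, service_cost_by_year, projection) {
  known <- c("governance", "his", "supply_chain",
             "emergency_risk_management", "health_financing_admin")
  bad <- setdiff(names(bm$overhead_rules), known)
  if (length(bad))
    stop("unknown overhead component key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  years <- projection$years
  pop_t <- apply(projection$population, 3, sum)
  svc <- setNames(numeric(length(years)), years)
  svc[names(service_cost_by_year)] <- service_cost_by_year
  purrr::map_dfr(names(bm$overhead_rules), function(key) {
    rule <- bm$overhead_rules[[key]]
    amt <- switch(rule$type,
                  per_capita = rule$value * pop_t,
                  pct_of_service = rule$value * unname(svc),
                  stop("unknown overhead rule type: ", rule$type, call. = FALSE))
    cost_line(profile$country_id, years, overhead_component(key), "none", amt)
  }) %>%
    dplyr::group_by(country_id, year, component, platform) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
}

#' All gross cost lines for one country-scenario
#'
#' @inheritParams workforce_plan
#' @param catalogue Intervention catalogue.
#' @param coverage Coverage matrix for the scenario.
#' @param price_multiplier Country price-level adjustment.
#' @return Tibble of cost lines (country_id, year, component, platform,
#'   amount), US$ 2014, undiscounted.
#' @export
country_cost_lines <- function(profile, catalogue, bm, coverage, projection,
                               scenario, price_multiplier = 1) {
  svc <- service_costs(profile, catalogue, coverage, projection, price_multiplier)
  svc_by_year <- svc %>% dplyr::group_by(year) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  wf <- workforce_plan(profile, bm, projection, scenario)
  inf <- infrastructure_plan(profile, bm, projection, scenario)
  ovh <- systems_overhead_costs(profile, bm,
                                setNames(svc_by_year$amount, svc_by_year$year),
                                projection)
  dplyr::bind_rows(svc, wf$lines, inf$lines, ovh)
}

#' Incremental costs of a scenario over the flatline counterfactual
#'
#' Differences scenario minus flatline per (country, year, component,
#' platform) after zero-filling missing keys, so a scenario identical to
#' flatline yields all-zero increments and increments plus flatline
#' reconstruct the scenario exactly.
#'
#' @param scenario_lines,flatline_lines Cost-line tibbles.
#' @return Cost-line tibble of per-key differences.
#' @export
incremental_costs <- function(scenario_lines, flatline_lines) {
  keys <- c("country_id", "year", "component", "platform")
  s <- scenario_lines %>% dplyr::group_by(dplyr::across(all_of(keys))) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  f <- flatline_lines %>% dplyr::group_by(dplyr::across(all_of(keys))) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
  dplyr::full_join(s, f, by = keys, suffix = c("_s", "_f")) %>%
    dplyr::mutate(amount = dplyr::coalesce(.data$amount_s, 0) -
                    dplyr::coalesce(.data$amount_f, 0)) %>%
    dplyr::select(dplyr::all_of(keys), amount) %>%
    dplyr::arrange(country_id, year, component, platform)
}

#' Scale cost lines by an efficiency factor
#'
#' High-efficiency (factor < 1) or low-efficiency (factor > 1) variants of a
#' cost stream; structure is unchanged.
#'
#' @param lines Cost-line tibble.
#' @param factor Positive scalar.
#' @return The lines with `amount` scaled.
#' @export
apply_efficiency <- function(lines, factor) {
  if (!is.finite(factor) || factor <= 0)
    stop("efficiency factor must be > 0", call. = FALSE)
  lines$amount <- lines$amount * factor
  lines
}

#' Total cost by year
#' @param lines Cost-line tibble.
#' @return Tibble (year, amount).
#' @export
cost_by_year <- function(lines) {
  lines %>% dplyr::group_by(year) %>%
    dplyr::summarise(amount = sum(amount), .groups = "drop")
}
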