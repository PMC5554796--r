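#' Service delivery platforms
#'
#' Four modes of provision with distinct scale-up dynamics: population-wide
#' policy measures and periodic schedulable/outreach services can expand
#' quickly in any setting; first-level (primary) clinical and specialised
#' clinical services are constrained by health-system strength.
#'
#' @return Character vector of the four platform labels.
#' @export
platforms <- function() {
  c("policy_population_wide", "periodic_outreach",
    "first_level_clinical", "specialised_clinical")
}

#' Programme areas in the intervention catalogue
#' @return Character vector of programme labels.
#' @export
programs <- function() {
  c("RMNCH", "immunisation", "HIV", "TB", "malaria", "NTD", "NCD",
    "mental_health", "nutrition", "emergency_care", "cross_sector")
}

#' Causes of death tracked by the impact model
#'
#' `stillbirth` is a pseudo-cause attached to births (so stillbirths averted
#' can be accounted alongside deaths averted); the remaining causes index the
#' `mortality_base` array of a profile.
#'
#' @return Character vector of cause labels.
#' @export
causes <- function() {
  c("stillbirth", "neonatal", "post_neonatal", "maternal", "cancer",
    "cvd_ncd", "tuberculosis", "hiv_aids", "malaria", "other")
}

mortality_causes <- function() setdiff(causes(), "stillbirth")

#' Construct an intervention catalogue row
#'
#' An intervention is a costed service: a delivery platform, a
#' population-in-need rule (fractions of age/sex cells needing the service
#' each year), unit requirements and prices, mortality-reduction effects, a
#' coverage frontier cap, and the share of its cost attributed to the health
#' sector (below 1 for cross-sectoral items such as water and sanitation).
#'
#' @param intervention_id Identifier.
#' @param program One of [programs()].
#' @param platform One of [platforms()].
#' @param pin_rule Tibble with columns `band`, `sex` (`"female"`, `"male"` or
#'   `"both"`) and `fraction` (fraction of that cell in need per year).
#' @param units_per_case Service units per person in need per year.
#' @param unit_price US$ 2014 per unit.
#' @param effects Tibble with columns `cause`, `effectiveness`,
#'   `affected_fraction`, `sex`, `age_lo`, `age_hi` (empty tibble for none).
#'   At full incremental coverage the cause-specific mortality rate in the
#'   targeted cells is multiplied by `1 - effectiveness * affected_fraction`.
#' @param frontier_cap Maximum attainable coverage in `[0,1]`.
#' @param health_sector_share Fraction of cost borne by the health sector.
#' @param program_cost_share Programme support cost (administration,
#'   supervision, campaigns) added as a fraction of the direct service cost.
#' @return A one-row tibble; bind rows to form a catalogue.
#' @export
intervention <- function(intervention_id, program, platform, pin_rule,
                         units_per_case, unit_price, effects = no_effects(),
                         frontier_cap = 0.95, health_sector_share = 1,
                         program_cost_share = 0.15) {
  stopifnot(program %in% programs(), platform %in% platforms())
  tibble::tibble(
    intervention_id = intervention_id, program = program, platform = platform,
    pin_rule = list(pin_rule), units_per_case = units_per_case,
    unit_price = unit_price, effects = list(effects),
    frontier_cap = frontier_cap, health_sector_share = health_sector_share,
    program_cost_share = program_cost_share)
}

#' @rdname intervention
#' @export
no_effects <- function() {
  tibble::tibble(cause = character(), effectiveness = numeric(),
                 affected_fraction = numeric(), sex = character(),
                 age_lo = numeric(), age_hi = numeric())
}

#' Validate an intervention catalogue
#'
#' @param catalogue Tibble of [intervention()] rows.
#' @return Character vector of violations (empty when valid).
#' @export
validate_catalogue <- function(catalogue) {
  v <- character()
  if (anyDuplicated(catalogue$intervention_id))
    v <- c(v, "intervention_id: duplicated identifiers")
  bad <- !catalogue$platform %in% platforms()
  if (any(bad)) v <- c(v, sprintf("platform: unknown value for %s",
                                  catalogue$intervention_id[bad][1]))
  rng <- function(x) any(!is.finite(x) | x < 0 | x > 1)
  if (rng(catalogue$frontier_cap))
    v <- c(v, "frontier_cap: values must lie in [0,1]")
  if (rng(catalogue$health_sector_share))
    v <- c(v, "health_sector_share: values must lie in [0,1]")
  if (any(catalogue$unit_price < 0) || any(catalogue$units_per_case < 0))
    v <- c(v, "unit_price/units_per_case: must be >= 0")
  for (i in seq_len(nrow(catalogue))) {
    ef <- catalogue$effects[[i]]
    if (nrow(ef) && any(ef$effectiveness * ef$affected_fraction > 1 + 1e-12))
      v <- c(v, sprintf("effects: effectiveness x affected_fraction > 1 for %s",
                        catalogue$intervention_id[i]))
    pr <- catalogue$pin_rule[[i]]
    if (rng(pr$fraction))
      v <- c(v, sprintf("pin_rule: fraction outside [0,1] for %s",
                        catalogue$intervention_id[i]))
  }
  v
}

#' Health-system input benchmarks
#'
#' Target input densities and unit costs used by the workforce,
#' infrastructure and overhead costing.  Default density targets are the
#' income-group-specific projected 2030 values of the ambitious scale-up
#' (per 1000 population for cadres, per 10 000 for facilities); unit-cost
#' defaults are stylised values for a low/middle-income context and should
#' be overridden with country evidence where available.
#'
#' @param income_group Income group whose default density targets to use.
#' @param workforce_density_target Named vector per 1000 population.
#' @param facility_density_target Named vector per 10 000 population.
#' @param facility_capex US$ per facility built, by level.
#' @param facility_opex_share Annual operating cost as a share of capex.
#' @param salary US$ per worker-year by cadre.
#' @param training_cost US$ per worker produced (one-off, on hiring).
#' @param overhead_rules Named list of per-component rules, each
#'   `list(type = "per_capita", value = US$/person)` or
#'   `list(type = "pct_of_service", value = fraction)`.
#' @return A list of class `benchmarks`.
#' @export
benchmarks <- function(income_group = "low",
                       workforce_density_target = NULL,
                       facility_density_target = c(primary = 1.0, hospital = 0.1),
                       facility_capex = c(primary = 250000, hospital = 5e6),
                       facility_opex_share = 0.1,
                       salary = c(doctor = 12000, nurse_midwife = 6000, other = 3000),
                       training_cost = c(doctor = 20000, nurse_midwife = 8000, other = 3000),
                       overhead_rules = default_overhead_rules()) {
  if (is.null(workforce_density_target)) {
    workforce_density_target <- switch(income_group,
      low = c(doctor = 1.18, nurse_midwife = 3.21, other = 3.30),
      lower_middle = c(doctor = 1.43, nurse_midwife = 4.07, other = 3.52),
      upper_middle = c(doctor = 1.78, nurse_midwife = 4.11, other = 3.07))
  }
  stopifnot(all(workforce_density_target >= 0), all(facility_density_target >= 0),
            all(salary >= 0), all(training_cost >= 0), all(facility_capex >= 0),
            facility_opex_share >= 0, facility_opex_share <= 1)
  structure(list(
    workforce_density_target = workforce_density_target,
    facility_density_target = facility_density_target,
    facility_capex = facility_capex,
    facility_opex_share = facility_opex_share,
    salary = salary, training_cost = training_cost,
    overhead_rules = overhead_rules), class = "benchmarks")
}

#' @rdname benchmarks
#' @export
default_overhead_rules <- function() {
  list(
    governance = list(type = "per_capita", value = 1.0),
    his = list(type = "per_capita", value = 0.5),
    supply_chain = list(type = "pct_of_service", value = 0.12),
    emergency_risk_management = list(type = "per_capita", value = 0.5),
    health_financing_admin = list(type = "pct_of_service", value = 0.03))
}

# map an overhead rule key to the reported cost component
overhead_component <- function(key) {
  if (key == "supply_chain") "supply_chain" else "governance_his_other"
}
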