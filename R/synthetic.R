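# run code under a temporary RNG seed, restoring any prior state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Synthetic-data generator configuration
#'
#' Distribution families are chosen for support correctness: log-normal for
#' monetary quantities, beta for fractions, gamma factors for rates, and
#' truncated normals for growth.  Defaults mirror the study conditions: a
#' 67-country ensemble (4 conflict-affected, 11 vulnerable, 15/16/21 in
#' health-system categories 1-3; 28 low-income, 21 lower-middle, 18
#' upper-middle) and a 187-intervention catalogue.
#'
#' @param seed Integer master seed; all draws derive from it.
#' @param n_countries Named counts per typology.
#' @param n_interventions Catalogue size.
#' @param gdp_meanlog,gdp_sdlog Log-normal GDP per person by income group.
#' @param growth_mean,growth_sd Annual GDP growth by typology (truncated to
#'   `[-0.02, 0.08]`).
#' @param coverage_mean Baseline-coverage beta mean by platform.
#' @param coverage_concentration Beta concentration (shape1 + shape2).
#' @param coverage_adjust Multiplier on the coverage mean by typology
#'   (weaker systems start lower).
#' @param mortality_level All-cause mortality scale factor by typology.
#' @param tfr_mean Total fertility rate by typology.
#' @param price_meanlog,price_sdlog Log-normal unit prices.
#' @param effectiveness_range,affected_fraction_range Uniform ranges for
#'   effect parameters.
#' @param affected_total_range Uniform range for the total share of a
#'   cause's deaths addressable by the catalogue; affected fractions of
#'   interventions targeting the same cause are scaled down to sum to this
#'   total, so each intervention acts on its own slice of cause deaths.
#' @param frontier_caps Named coverage caps by programme (0.60 for NCD and
#'   mental-health management, 0.95 for maternal/child and immunisation
#'   services, intermediate elsewhere).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1,
    n_countries = c(conflict = 4, vulnerable = 11, hs1 = 15, hs2 = 16, hs3 = 21),
    n_interventions = 187,
    gdp_meanlog = c(low = log(700), lower_middle = log(2200), upper_middle = log(7500)),
    gdp_sdlog = 0.3,
    growth_mean = c(conflict = 0.010, vulnerable = 0.020, hs1 = 0.025,
                    hs2 = 0.030, hs3 = 0.035),
    growth_sd = 0.005,
    coverage_mean = c(policy_population_wide = 0.40, periodic_outreach = 0.50,
                      first_level_clinical = 0.35, specialised_clinical = 0.20),
    coverage_concentration = 12,
    coverage_adjust = c(conflict = 0.55, vulnerable = 0.70, hs1 = 0.85,
                        hs2 = 1.00, hs3 = 1.15),
    mortality_level = c(conflict = 1.6, vulnerable = 1.4, hs1 = 1.25,
                        hs2 = 1.0, hs3 = 0.8),
    tfr_mean = c(conflict = 5.2, vulnerable = 4.6, hs1 = 4.2, hs2 = 2.9, hs3 = 2.1),
    price_meanlog = log(1.5), price_sdlog = 0.8,
    effectiveness_range = c(0.3, 0.8),
    affected_fraction_range = c(0.2, 0.9),
    affected_total_range = c(0.5, 0.9),
    frontier_caps = c(RMNCH = 0.95, immunisation = 0.95, nutrition = 0.95,
                      HIV = 0.90, TB = 0.90, malaria = 0.90, NTD = 0.90,
                      NCD = 0.60, mental_health = 0.60, emergency_care = 0.80,
                      cross_sector = 0.80)) {
  structure(as.list(environment()), class = "generator_config")
}

# stylised all-cause mortality schedule (deaths per person-year) by band
base_mortality_schedule <- function() {
  c(0.045, 0.0030, 0.0012, 0.0010, 0.0015, 0.0020, 0.0025, 0.0030, 0.0038,
    0.0050, 0.0070, 0.0100, 0.0150, 0.0220, 0.0340, 0.0520, 0.0820, 0.1300,
    0.2200)
}

# cause decomposition of all-cause mortality by band and sex
base_cause_shares <- function() {
  cs <- mortality_causes()  # 9 causes
  sh <- array(0, c(19, 2, length(cs)),
              dimnames = list(age_bands()$band, sexes(), cs))
  set_row <- function(bands, sex, values) {
    for (b in bands) for (s in sex) sh[b, s, names(values)] <<- values
  }
  both <- sexes()
  set_row("0", both, c(neonatal = 0.70, post_neonatal = 0, malaria = 0.10,
                       hiv_aids = 0.03, other = 0.17))
  set_row("1-4", both, c(post_neonatal = 0.55, malaria = 0.18, hiv_aids = 0.04,
                         tuberculosis = 0.03, other = 0.20))
  kid <- c("5-9", "10-14")
  set_row(kid, both, c(malaria = 0.12, tuberculosis = 0.05, hiv_aids = 0.05,
                       cancer = 0.03, cvd_ncd = 0.05, other = 0.70))
  adult <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
  set_row(adult, "female", c(maternal = 0.10, hiv_aids = 0.20, tuberculosis = 0.12,
                             cvd_ncd = 0.15, cancer = 0.08, malaria = 0.05,
                             other = 0.30))
  set_row(adult, "male", c(hiv_aids = 0.20, tuberculosis = 0.14, cvd_ncd = 0.18,
                           cancer = 0.08, malaria = 0.05, other = 0.35))
  old <- age_bands()$band[age_bands()$start >= 50]
  set_row(old, both, c(cvd_ncd = 0.42, cancer = 0.20, tuberculosis = 0.05,
                       hiv_aids = 0.02, other = 0.31))
  sh
}

# stylised population pyramid: counts by band x sex for a given total and TFR
build_age_structure <- function(total, tfr) {
  ab <- age_bands()
  mid <- ifelse(is.finite(ab$width), ab$start + ab$width / 2, 87.5)
  w_eff <- ifelse(is.finite(ab$width), ab$width, 5)
  decay <- 0.010 + 0.006 * max(0, tfr - 2)
  w <- w_eff * exp(-decay * mid)
  counts <- total * w / sum(w)
  m <- cbind(female = counts / 2, male = counts / 2)
  rownames(m) <- ab$band
  m
}

fertility_from_tfr <- function(tfr) {
  shape <- c(0.10, 0.22, 0.25, 0.20, 0.13, 0.07, 0.03)
  setNames(tfr * shape / 5, fertility_bands())
}

#' Generate one synthetic country profile
#'
#' Draws a country consistent with its typology and income group: weaker
#' typologies get lower baseline coverage, input densities and growth, and
#' higher mortality and fertility.  All draws are truncated into the type
#' invariants, so every generated profile passes [validate_profile()], and
#' the same seed reproduces the profile bit for bit.
#'
#' @param config A [generator_config()].
#' @param typology,income_group Country classification.
#' @param catalogue Intervention catalogue (baseline coverage is drawn per
#'   intervention).
#' @param seed Integer seed for this country.
#' @param country_id Identifier (default derived from the seed).
#' @return A validated [country_profile()].
#' @export
generate_country <- function(config, typology, income_group, catalogue, seed,
                             country_id = sprintf("SYN%06d", seed %% 1000000L)) {
  with_seed(seed, {
    gdp <- rlnorm(1, config$gdp_meanlog[[income_group]], config$gdp_sdlog)
    growth <- pmin(0.08, pmax(-0.02,
      rnorm(15, config$growth_mean[[typology]], config$growth_sd)))
    total_pop <- pmin(5e8, pmax(5e5, rlnorm(1, log(2e7), 1.1)))
    tfr <- max(0.8, rnorm(1, config$tfr_mean[[typology]], 0.3))
    pop <- build_age_structure(total_pop, tfr)
    level <- config$mortality_level[[typology]] * rgamma(1, 25, 25)
    shares <- base_cause_shares()
    noise <- rgamma(length(mortality_causes()), 25, 25)
    mort <- array(0, dim(shares), dimnames = dimnames(shares))
    sched <- base_mortality_schedule()
    for (k in seq_along(mortality_causes()))
      mort[, , k] <- sched * level * shares[, , k] * noise[k]
    capw <- config$coverage_adjust[[typology]]
    mu <- pmin(0.9, pmax(0.02, config$coverage_mean[catalogue$platform] * capw))
    cc <- config$coverage_concentration
    cov <- rbeta(nrow(catalogue), mu * cc, (1 - mu) * cc)
    cov <- pmin(0.95, pmax(0.005, cov))
    names(cov) <- catalogue$intervention_id
    cap_factor <- c(conflict = 0.25, vulnerable = 0.4, hs1 = 0.55,
                    hs2 = 0.85, hs3 = 1.2)[[typology]]
    wd <- c(doctor = runif(1, 0.15, 0.5), nurse_midwife = runif(1, 0.5, 1.5),
            other = runif(1, 0.5, 1.5)) * cap_factor
    fd <- c(primary = runif(1, 0.3, 0.9), hospital = runif(1, 0.03, 0.09)) * cap_factor
    rev_share <- runif(1, 0.15, 0.30)
    health_share <- runif(1, 0.06, 0.12)
    gghe <- gdp * rev_share * health_share
    the <- gghe * (1 + runif(1, 0.5, 1.5))
    country_profile(
      country_id = country_id, income_group = income_group, typology = typology,
      population_base = pop, fertility_rate = fertility_from_tfr(tfr),
      mortality_base = mort, stillbirth_rate = runif(1, 0.012, 0.025),
      baseline_coverage = cov, workforce_density_base = wd,
      facility_density_base = fd, gdp_per_capita_2015 = gdp,
      gdp_growth = growth, govt_revenue_share = rev_share,
      health_share_of_govt = health_share,
      the_per_capita_2014 = the, gghe_per_capita_2014 = gghe)
  })
}

program_platform_menu <- function() {
  list(RMNCH = c("periodic_outreach", "first_level_clinical"),
       immunisation = "periodic_outreach",
       HIV = c("first_level_clinical", "periodic_outreach"),
       TB = c("first_level_clinical", "specialised_clinical"),
       malaria = c("periodic_outreach", "policy_population_wide"),
       NTD = "periodic_outreach",
       NCD = c("first_level_clinical", "specialised_clinical", "policy_population_wide"),
       mental_health = c("first_level_clinical", "specialised_clinical"),
       nutrition = c("periodic_outreach", "first_level_clinical"),
       emergency_care = "specialised_clinical",
       cross_sector = "policy_population_wide")
}

program_pin_menu <- function(program) {
  pick <- function(bands, sex, lo, hi)
    tibble::tibble(band = bands, sex = sex, fraction = runif(1, lo, hi))
  adult <- bands_in_range(15, 49); older <- bands_in_range(30, 100)
  switch(program,
    RMNCH = pick(adult, "female", 0.03, 0.10),
    immunisation = pick(c("0", "1-4"), "both", 0.8, 1.0),
    HIV = pick(adult, "both", 0.01, 0.05),
    TB = pick(bands_in_range(15, 100), "both", 0.002, 0.006),
    malaria = pick(c("0", "1-4", "5-9"), "both", 0.10, 0.30),
    NTD = pick(bands_in_range(5, 14), "both", 0.20, 0.50),
    NCD = pick(older, "both", 0.05, 0.20),
    mental_health = pick(bands_in_range(15, 100), "both", 0.02, 0.08),
    nutrition = pick(c("0", "1-4"), "both", 0.10, 0.40),
    emergency_care = pick(age_bands()$band, "both", 0.002, 0.010),
    cross_sector = pick(age_bands()$band, "both", 0.10, 0.30))
}

program_effect_menu <- function(program, config) {
  e <- runif(1, config$effectiveness_range[1], config$effectiveness_range[2])
  af <- runif(1, config$affected_fraction_range[1], config$affected_fraction_range[2])
  row <- function(cause, sex = "both", lo = 0, hi = 100)
    tibble::tibble(cause = cause, effectiveness = e, affected_fraction = af,
                   sex = sex, age_lo = lo, age_hi = hi)
  switch(program,
    RMNCH = {
      cause <- sample(c("maternal", "neonatal", "stillbirth", "post_neonatal"), 1)
      switch(cause,
             maternal = row("maternal", "female", 15, 49),
             neonatal = row("neonatal", lo = 0, hi = 0),
             stillbirth = row("stillbirth"),
             post_neonatal = row("post_neonatal", lo = 0, hi = 4))
    },
    immunisation = row("post_neonatal", lo = 0, hi = 4),
    HIV = row("hiv_aids"),
    TB = row("tuberculosis"),
    malaria = row("malaria", lo = 0, hi = 14),
    NTD = row("other", lo = 5, hi = 14),
    NCD = row(sample(c("cvd_ncd", "cancer"), 1), lo = 30, hi = 100),
    mental_health = row("cvd_ncd", lo = 15, hi = 100),
    nutrition = row("post_neonatal", lo = 0, hi = 4),
    emergency_care = row("other"),
    cross_sector = row("post_neonatal", lo = 0, hi = 4))
}

#' Generate a synthetic intervention catalogue
#'
#' The default catalogue has 187 interventions spread over the eleven
#' programme areas with platform mixes characteristic of each (immunisation
#' via periodic outreach, NCD management via clinical platforms, etc.).
#' Frontier caps follow the configuration table (NCD and mental-health
#' management 0.60, maternal/child and immunisation services 0.95);
#' cross-sectoral items carry a health-sector share below 1.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default the config's).
#' @return Catalogue tibble passing [validate_catalogue()].
#' @export
generate_interventions <- function(config, seed = config$seed) {
  base_counts <- c(RMNCH = 40, immunisation = 15, HIV = 15, TB = 10,
                   malaria = 10, NTD = 8, NCD = 40, mental_health = 12,
                   nutrition = 12, emergency_care = 10, cross_sector = 15)
  n <- config$n_interventions
  counts <- floor(base_counts * n / sum(base_counts))
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- base_counts * n / sum(base_counts) - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  menu <- program_platform_menu()
  with_seed(seed, {
    rows <- purrr::imap(counts, function(k, prog) {
      if (k == 0) return(NULL)
      purrr::map(seq_len(k), function(j) {
        platform <- menu[[prog]][1 + (j - 1) %% length(menu[[prog]])]
        intervention(
          intervention_id = sprintf("%s_%02d", tolower(prog), j),
          program = prog, platform = platform,
          pin_rule = program_pin_menu(prog),
          units_per_case = round(runif(1, 1, 6)),
          unit_price = rlnorm(1, config$price_meanlog, config$price_sdlog),
          effects = program_effect_menu(prog, config),
          frontier_cap = config$frontier_caps[[prog]],
          health_sector_share = if (prog == "cross_sector") runif(1, 0.2, 0.6) else 1,
          program_cost_share = runif(1, 0.05, 0.25))
      })
    })
    cat_tbl <- dplyr::bind_rows(purrr::flatten(rows))
    # affected fractions partition each cause's deaths: scale within cause so
    # the slices sum to a drawn total (never scaled up)
    all_eff <- dplyr::bind_rows(cat_tbl$effects)
    for (cs in unique(all_eff$cause)) {
      tot <- sum(all_eff$affected_fraction[all_eff$cause == cs])
      target <- runif(1, config$affected_total_range[1],
                      config$affected_total_range[2])
      if (tot > target) {
        sc <- target / tot
        cat_tbl$effects <- purrr::map(cat_tbl$effects, function(ef) {
          ef$affected_fraction[ef$cause == cs] <-
            ef$affected_fraction[ef$cause == cs] * sc
          ef
        })
      }
    }
    cat_tbl
  })
}

#' Generate the default synthetic country ensemble
#'
#' Assigns income groups within typologies so the ensemble covers all five
#' typologies and all three income groups (defaults reproduce a 67-country
#' composition: 28 low, 21 lower-middle, 18 upper-middle income).
#'
#' @param config A [generator_config()].
#' @param catalogue Catalogue from [generate_interventions()].
#' @return List of validated profiles.
#' @export
generate_profiles <- function(config, catalogue) {
  assign_income <- list(
    conflict = c(low = 4, lower_middle = 0, upper_middle = 0),
    vulnerable = c(low = 8, lower_middle = 3, upper_middle = 0),
    hs1 = c(low = 12, lower_middle = 3, upper_middle = 0),
    hs2 = c(low = 4, lower_middle = 9, upper_middle = 3),
    hs3 = c(low = 0, lower_middle = 6, upper_middle = 15))
  plan <- purrr::imap_dfr(config$n_countries, function(k, typ) {
    shares <- assign_income[[typ]]
    inc <- rep(names(shares), round(shares * k / sum(shares)))
    inc <- c(inc, rep("lower_middle", max(0, k - length(inc))))[seq_len(k)]
    tibble::tibble(typology = typ, income_group = inc)
  })
  purrr::map(seq_len(nrow(plan)), function(i) {
    generate_country(config, plan$typology[i], plan$income_group[i], catalogue,
                     seed = (config$seed + 7919L * i) %% .Machine$integer.max,
                     country_id = sprintf("SYN%03d", i))
  })
}

#' Deterministic worked fixture
#'
#' Two small hard-coded country profiles, a three-intervention catalogue
#' (an outreach immunisation service, a clinical NCD-management service and
#' a population-wide tobacco policy) and round-number benchmarks.  Every
#' number is fixed, so end-to-end runs on the fixture are exactly
#' reproducible and can be checked against independently recomputed values.
#'
#' @return List with `profiles` (2), `catalogue` (3 rows), `benchmarks`.
#' @export
worked_fixture <- function() {
  cat3 <- dplyr::bind_rows(
    intervention("measles_vacc", "immunisation", "periodic_outreach",
                 tibble::tibble(band = c("0", "1-4"), sex = "both", fraction = 0.9),
                 units_per_case = 1, unit_price = 25,
                 effects = tibble::tibble(cause = "post_neonatal",
                                          effectiveness = 0.5,
                                          affected_fraction = 0.5,
                                          sex = "both", age_lo = 0, age_hi = 4),
                 frontier_cap = 0.95, health_sector_share = 1,
                 program_cost_share = 0.10),
    intervention("ncd_htn", "NCD", "first_level_clinical",
                 tibble::tibble(band = bands_in_range(30, 100), sex = "both",
                                fraction = 0.12),
                 units_per_case = 4, unit_price = 8,
                 effects = tibble::tibble(cause = "cvd_ncd", effectiveness = 0.35,
                                          affected_fraction = 0.5, sex = "both",
                                          age_lo = 30, age_hi = 100),
                 frontier_cap = 0.60, health_sector_share = 1,
                 program_cost_share = 0.15),
    intervention("tobacco_policy", "NCD", "policy_population_wide",
                 tibble::tibble(band = bands_in_range(15, 100), sex = "both",
                                fraction = 1),
                 units_per_case = 1, unit_price = 0.5,
                 effects = tibble::tibble(cause = "cvd_ncd", effectiveness = 0.2,
                                          affected_fraction = 0.3, sex = "both",
                                          age_lo = 15, age_hi = 100),
                 frontier_cap = 0.95, health_sector_share = 1,
                 program_cost_share = 0.05))
  mk_profile <- function(id, income, typ, total_pop, tfr, level, gdp, growth,
                         cov, wd, fd) {
    shares <- base_cause_shares()
    sched <- base_mortality_schedule()
    mort <- array(0, dim(shares), dimnames = dimnames(shares))
    for (k in seq_len(dim(shares)[3])) mort[, , k] <- sched * level * shares[, , k]
    rev_share <- 0.20; health_share <- 0.08
    gghe <- gdp * rev_share * health_share
    country_profile(
      country_id = id, income_group = income, typology = typ,
      population_base = build_age_structure(total_pop, tfr),
      fertility_rate = fertility_from_tfr(tfr),
      mortality_base = mort, stillbirth_rate = 0.02,
      baseline_coverage = cov, workforce_density_base = wd,
      facility_density_base = fd, gdp_per_capita_2015 = gdp,
      gdp_growth = rep(growth, 15), govt_revenue_share = rev_share,
      health_share_of_govt = health_share,
      the_per_capita_2014 = gghe * 2, gghe_per_capita_2014 = gghe)
  }
  cov_names <- cat3$intervention_id
  profiles <- list(
    mk_profile("ALPHA", "low", "hs1", 1e7, 4.5, 1.3, 800, 0.025,
               setNames(c(0.60, 0.20, 0.30), cov_names),
               c(doctor = 0.2, nurse_midwife = 1.0, other = 1.0),
               c(primary = 0.4, hospital = 0.05)),
    mk_profile("BETA", "lower_middle", "hs3", 5e7, 2.2, 0.9, 3000, 0.03,
               setNames(c(0.85, 0.45, 0.50), cov_names),
               c(doctor = 1.0, nurse_midwife = 2.5, other = 2.5),
               c(primary = 0.8, hospital = 0.08)))
  bm <- benchmarks(
    workforce_density_target = c(doctor = 1.0, nurse_midwife = 3.0, other = 3.0),
    facility_density_target = c(primary = 1.0, hospital = 0.1),
    facility_capex = c(primary = 200000, hospital = 4e6),
    facility_opex_share = 0.1,
    salary = c(doctor = 10000, nurse_midwife = 5000, other = 2500),
    training_cost = c(doctor = 15000, nurse_midwife = 6000, other = 2000))
  list(profiles = profiles, catalogue = cat3, benchmarks = bm)
}
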