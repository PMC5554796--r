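# a fabricated projection with a fixed population, for unit-level costing
fake_projection <- function(pop_by_band, years = projection_years()) {
  pop <- matrix(0, 19, 2, dimnames = list(age_bands()$band, sexes()))
  for (b in names(pop_by_band)) pop[b, ] <- pop_by_band[[b]] / 2
  arr <- array(rep(pop, length(years)), c(19, 2, length(years)),
               dimnames = list(age_bands()$band, sexes(), years))
  structure(list(population = arr, years = years),
            class = "population_projection")
}

fx <- worked_fixture()
p1 <- fx$profiles[[1]]

test_that("population in need is the band-by-band product sum", {
  proj <- fake_projection(list("0" = 4000, "1-4" = 16000, "15-19" = 10000))
  none <- intervention("x", "NCD", "first_level_clinical",
                       tibble::tibble(band = "0", sex = "both", fraction = 0),
                       1, 1)
  expect_equal(population_in_need(p1, none, 2020, proj), 0)
  one_band <- intervention("y", "NCD", "first_level_clinical",
                           tibble::tibble(band = "15-19", sex = "both", fraction = 0.1),
                           1, 1)
  expect_equal(population_in_need(p1, one_band, 2020, proj), 1000)
  multi <- intervention("z", "RMNCH", "periodic_outreach",
                        tibble::tibble(band = c("0", "1-4", "15-19"),
                                       sex = c("both", "female", "male"),
                                       fraction = c(0.5, 0.25, 0.1)),
                        1, 1)
  hand <- 4000 * 0.5 + 8000 * 0.25 + 5000 * 0.1
  expect_equal(population_in_need(p1, multi, 2020, proj), hand)
  expect_error(population_in_need(p1, multi, 2040, proj), "outside projection")
})

test_that("intervention cost is quantities times price", {
  proj <- fake_projection(list("15-19" = 100000))
  iv <- intervention("t", "HIV", "first_level_clinical",
                     tibble::tibble(band = "15-19", sex = "both", fraction = 0.01),
                     units_per_case = 2, unit_price = 3, program_cost_share = 0)
  lines <- intervention_cost(p1, iv, 2020, coverage = 0.5, proj)
  expect_equal(sum(lines$amount), 1000 * 0.5 * 2 * 3)
  expect_equal(sum(intervention_cost(p1, iv, 2020, 0, proj)$amount), 0)
  expect_error(intervention_cost(p1, iv, 2020, 1.5, proj), "coverage")
})

test_that("vectorised service costing equals the spreadsheet-style oracle", {
  amb <- scenario_spec("ambitious")
  cov <- build_coverage_paths(p1, fx$catalogue, amb)
  proj <- project_population(p1, fx$catalogue, cov)
  lines <- uhcproj:::service_costs(p1, fx$catalogue, cov, proj)
  expect_equal(sum(lines$amount),
               oracle_service_cost_total(p1, fx$catalogue, cov, proj),
               tolerance = 1e-10)
  expect_true(all(lines$amount >= 0))
  expect_setequal(unique(lines$component), c("drugs_supplies", "program_costs"))
})

test_that("workforce plan closes density gaps linearly and never sheds staff", {
  pop <- 1e7
  proj <- fake_projection(setNames(as.list(rep(pop / 19, 19)), age_bands()$band))
  prof <- p1
  prof$population_base <- proj$population[, , 1]
  bm <- benchmarks(workforce_density_target =
                     c(doctor = 0.2, nurse_midwife = 3.21, other = 1.0))
  prof$workforce_density_base <- c(doctor = 0.2, nurse_midwife = 1.0, other = 1.0)
  plan <- workforce_plan(prof, bm, proj, scenario_spec("ambitious"))
  nurses <- plan$staffing[plan$staffing$cadre == "nurse_midwife", ]
  # (3.21 - 1.00) per 1000 on a 10M population: 22 100 additional nurses
  expect_equal(nurses$headcount[nurses$year == 2030] - 1.0 * pop / 1000, 22100,
               tolerance = 1e-6)
  # density already at target, constant population: no hires
  docs <- plan$staffing[plan$staffing$cadre == "doctor", ]
  expect_equal(sum(docs$hires), 0)
  # linear interpolation oracle, year by year
  cur <- 1.0 * pop / 1000; req <- 3.21 * pop / 1000
  expected <- cur + (2016:2030 - 2015) / 15 * (req - cur)
  expect_equal(nurses$headcount, expected, tolerance = 1e-9)
  expect_true(all(diff(nurses$headcount) >= 0))
})

test_that("infrastructure capex peaks in 2029 and conserves total cost", {
  proj <- fake_projection(setNames(as.list(rep(5e6 / 19, 19)), age_bands()$band))
  prof <- p1
  prof$population_base <- proj$population[, , 1]
  bm <- fx$benchmarks
  plan <- infrastructure_plan(prof, bm, proj, scenario_spec("ambitious"))
  sched <- plan$schedule[plan$schedule$level == "primary", ]
  expect_equal(sched$year[which.max(sched$built)], 2029)
  expect_true(all(sched$year <= 2029))
  gap <- bm$facility_density_target[["primary"]] * 5e6 / 10000 -
    prof$facility_density_base[["primary"]] * 5e6 / 10000
  expect_equal(sum(sched$built), gap, tolerance = 1e-9)
  # stock at/above target: nothing built
  rich <- prof
  rich$facility_density_base <- c(primary = 2, hospital = 0.5)
  plan2 <- infrastructure_plan(rich, bm, proj, scenario_spec("ambitious"))
  expect_equal(sum(plan2$schedule$built), 0)
  expect_equal(sum(plan2$lines$amount), 0)
})

test_that("overhead rules scale with population or service cost as configured", {
  proj <- fake_projection(setNames(as.list(rep(1e6 / 19, 19)), age_bands()$band))
  svc <- setNames(rep(5e6, 15), projection_years())
  bm0 <- fx$benchmarks
  bm0$overhead_rules <- list(governance = list(type = "per_capita", value = 0),
                             supply_chain = list(type = "pct_of_service", value = 0))
  expect_equal(sum(systems_overhead_costs(p1, bm0, svc, proj)$amount), 0)
  bm1 <- fx$benchmarks
  bm1$overhead_rules <- list(governance = list(type = "per_capita", value = 2))
  lines <- systems_overhead_costs(p1, bm1, svc, proj)
  expect_equal(unique(lines$amount), 2e6)
  # mixed rules equal the rule-by-rule oracle
  bm2 <- fx$benchmarks
  got <- systems_overhead_costs(p1, bm2, svc, proj)
  oracle <- sum(vapply(bm2$overhead_rules, function(r)
    if (r$type == "per_capita") r$value * 1e6 * 15 else r$value * sum(svc),
    numeric(1)))
  expect_equal(sum(got$amount), oracle, tolerance = 1e-9)
  bm3 <- fx$benchmarks
  bm3$overhead_rules <- list(unknown_thing = list(type = "per_capita", value = 1))
  expect_error(systems_overhead_costs(p1, bm3, svc, proj), "unknown overhead")
})

test_that("incremental differencing is exact and reconstructs the scenario", {
  amb <- scenario_spec("ambitious")
  cov <- build_coverage_paths(p1, fx$catalogue, amb)
  proj <- project_population(p1, fx$catalogue, cov)
  lines <- country_cost_lines(p1, fx$catalogue, fx$benchmarks, cov, proj, amb)
  zero <- incremental_costs(lines, lines)
  expect_equal(max(abs(zero$amount)), 0)
  # flatline missing a key entirely: increment is the full scenario amount
  extra <- dplyr::bind_rows(lines,
    tibble::tibble(country_id = "ALPHA", year = 2020L, component = "workforce",
                   platform = "extra", amount = 5e6))
  inc <- incremental_costs(extra, lines)
  expect_equal(sum(inc$amount), 5e6)
  # additivity: increments + flatline = scenario, key by key
  flat_cov <- build_coverage_paths(p1, fx$catalogue, scenario_spec("flatline"))
  flat_proj <- project_population(p1, fx$catalogue, flat_cov)
  flat_lines <- country_cost_lines(p1, fx$catalogue, fx$benchmarks, flat_cov,
                                   flat_proj, scenario_spec("flatline"))
  inc2 <- incremental_costs(lines, flat_lines)
  agg <- function(l) dplyr::arrange(
    dplyr::summarise(dplyr::group_by(l, year, component, platform),
                     amount = sum(amount), .groups = "drop"),
    year, component, platform)
  s <- agg(lines); f <- agg(flat_lines); i <- agg(inc2)
  j <- dplyr::full_join(f, i, by = c("year", "component", "platform"),
                        suffix = c("_f", "_i"))
  j[is.na(j)] <- 0
  j <- dplyr::left_join(j, s, by = c("year", "component", "platform"))
  j$amount[is.na(j$amount)] <- 0
  expect_equal(j$amount_f + j$amount_i, j$amount, tolerance = 1e-9)
})

test_that("efficiency scaling is linear in the factor", {
  lines <- tibble::tibble(country_id = "A", year = 2020L,
                          component = "workforce", platform = "none",
                          amount = c(100, 250))
  expect_equal(apply_efficiency(lines, 1)$amount, c(100, 250))
  expect_equal(apply_efficiency(lines, 0.9)$amount[1], 90)
  f <- runif(1, 0.5, 1.5)
  expect_equal(sum(apply_efficiency(lines, f)$amount), f * 350, tolerance = 1e-12)
  expect_error(apply_efficiency(lines, 0), "factor")
  expect_error(apply_efficiency(lines, -1), "factor")
})
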