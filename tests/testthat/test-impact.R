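test_that("mortality adjustment is a permutation-invariant product", {
  expect_equal(adjusted_mortality(0.01, 0, 0, 0), 0.01)
  expect_equal(adjusted_mortality(0.01, 0.5, 1, 0.4), 0.008)
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    e <- runif(k); af <- runif(k); dc <- runif(k)
    m <- runif(1, 0.001, 0.3)
    direct <- m * prod(1 - e * af * dc)
    expect_equal(adjusted_mortality(m, e, af, dc), direct, tolerance = 1e-12)
    o <- sample(k)
    expect_equal(adjusted_mortality(m, e[o], af[o], dc[o]),
                 adjusted_mortality(m, e, af, dc), tolerance = 1e-15)
    expect_lte(adjusted_mortality(m, e, af, dc), m)
    expect_gt(adjusted_mortality(m, e, af, dc), 0)
  }
  expect_error(adjusted_mortality(0.01, 1.5, 1, 1), "effectiveness")
  expect_error(adjusted_mortality(0.01, 0.5, 1, -0.1), "coverage_delta")
})

test_that("population is conserved without births and deaths", {
  toy <- toy_inputs(mort_scale = 0, fert_level = 0)
  proj <- project_cohorts(toy$pop0, toy$mort, toy$fert, toy$widths,
                          years = 2016:2025)
  totals <- apply(proj$population, 3, sum)
  expect_equal(max(abs(totals - sum(toy$pop0))) / sum(toy$pop0), 0,
               tolerance = 1e-9)
})

test_that("the engine matches a hand-stepped cohort oracle on a 3-band toy", {
  toy <- toy_inputs(mort_scale = 1, fert_level = 0.08)
  proj <- project_cohorts(toy$pop0, toy$mort, toy$fert, toy$widths,
                          years = 2016:2020)
  oracle <- oracle_project(toy$pop0, toy$mort, toy$fert, toy$widths, 5)
  expect_equal(unname(proj$population), unname(oracle$population),
               tolerance = 1e-12)
  expect_equal(unname(proj$deaths), unname(oracle$deaths), tolerance = 1e-12)
})

test_that("scale-up lowers deaths and raises population every year", {
  fx <- worked_fixture()
  p <- fx$profiles[[1]]
  cov_a <- build_coverage_paths(p, fx$catalogue, scenario_spec("ambitious"))
  cov_f <- build_coverage_paths(p, fx$catalogue, scenario_spec("flatline"))
  pa <- project_population(p, fx$catalogue, cov_a)
  pf <- project_population(p, fx$catalogue, cov_f)
  expect_true(all(apply(pa$population, 3, sum) >= apply(pf$population, 3, sum) - 1e-9))
  expect_true(all(cumsum(apply(pa$deaths, 4, sum)) <=
                    cumsum(apply(pf$deaths, 4, sum)) + 1e-9))
  da <- deaths_averted(pa, pf)
  # all-cause deaths averted are non-negative every year; individual causes
  # may dip below zero through competing risks among extra survivors
  by_year <- tapply(da$averted, da$year, sum)
  expect_true(all(by_year >= -1e-9))
  expect_gt(sum(da$averted), 0)
  zero <- deaths_averted(pf, pf)
  expect_equal(max(abs(zero$averted)), 0)
})

test_that("life expectancy honours constant-hazard and scaling limits", {
  mu <- 0.02
  lt <- life_table(rep(mu, 19))
  expect_equal(lt$e[1], 1 / mu, tolerance = 0.02)
  lt2 <- life_table(rep(2 * mu, 19))
  expect_equal(lt2$e[1], lt$e[1] / 2, tolerance = 0.02)
  expect_error(life_table(c(rep(0.01, 18), 0)), "open-ended band")
})

test_that("life table matches the sequential oracle on random rate vectors", {
  set.seed(9)
  widths <- age_bands()$width
  for (i in 1:50) {
    m <- rgamma(19, shape = 2, rate = 60) + 1e-4
    lt <- life_table(m)
    expect_equal(lt$e[1], oracle_e0(m, widths), tolerance = 1e-9)
    expect_true(all(lt$q >= 0 & lt$q <= 1))
    expect_true(all(diff(lt$l) <= 1e-12))
  }
  # 5-band toy table against the same hand-computed arithmetic
  m5 <- c(0.03, 0.004, 0.01, 0.05, 0.2)
  w5 <- c(1, 4, 10, 10, Inf)
  expect_equal(life_table(m5, w5)$e[1], oracle_e0(m5, w5), tolerance = 1e-9)
})

test_that("life-expectancy gains compare the right scenarios", {
  m <- rep(0.02, 19)
  lt <- life_table(m)
  g0 <- le_gains(lt, lt, lt)
  expect_equal(g0$gain_vs_2015, 0)
  expect_equal(g0$gain_vs_flatline, 0)
  lt_flat <- life_table(m * 0.95)   # flatline itself improves
  lt_scen <- life_table(m * 0.85)   # scenario improves more
  g <- le_gains(lt_scen, lt_flat, lt)
  expect_gt(g$gain_vs_flatline, 0)
  expect_gt(g$gain_vs_2015, g$gain_vs_flatline)
  expect_error(le_gains(life_table(c(0.1, 0.2), c(1, Inf)), lt, lt), "band structure")
})

test_that("healthy life-years follow the direct-sum oracle", {
  fx <- worked_fixture()
  p <- fx$profiles[[1]]
  cov_a <- build_coverage_paths(p, fx$catalogue, scenario_spec("ambitious"))
  cov_f <- build_coverage_paths(p, fx$catalogue, scenario_spec("flatline"))
  pa <- project_population(p, fx$catalogue, cov_a)
  pf <- project_population(p, fx$catalogue, cov_f)
  # zero prevalence: healthy life-years equal total person-years
  none <- default_conditions()[0, ]
  h0 <- healthy_life_years(pa, pf, cov_a, cov_f, fx$catalogue, none)
  expect_equal(h0$by_year$hly_scenario, unname(apply(pa$population, 3, sum)))
  # identical scenarios: zero gain
  hsame <- healthy_life_years(pf, pf, cov_f, cov_f, fx$catalogue)
  expect_equal(max(abs(hsame$by_year$gain)), 0)
  # one condition, weight 0.2, full prevalence-halving at delta = 0.5
  cond <- tibble::tibble(condition = "c", program = "NCD", prevalence = 0.10,
                         disability_weight = 0.2, reduction_factor = 1)
  h1 <- healthy_life_years(pa, pf, cov_a, cov_f, fx$catalogue, cond)
  ncd_ids <- fx$catalogue$intervention_id[fx$catalogue$program == "NCD"]
  dbar <- colMeans(pmax(cov_a[ncd_ids, , drop = FALSE] -
                          p$baseline_coverage[ncd_ids], 0))
  pop_s <- apply(pa$population, 3, sum); pop_f <- apply(pf$population, 3, sum)
  oracle <- pop_s * (1 - 0.10 * (1 - dbar) * 0.2) - pop_f * (1 - 0.10 * 0.2)
  expect_equal(h1$by_year$gain, unname(oracle), tolerance = 1e-9)
  # programme attribution sums to the total gain
  tot_by_prog <- tapply(h1$by_program$gain, h1$by_program$year, sum)
  expect_equal(as.numeric(tot_by_prog[as.character(h1$by_year$year)]),
               h1$by_year$gain, tolerance = 1e-9)
  bad <- cond; bad$prevalence <- 1; bad$disability_weight <- 1.000
  bad2 <- dplyr::bind_rows(bad, bad)
  expect_error(healthy_life_years(pa, pf, cov_a, cov_f, fx$catalogue, bad2),
               "combined disability")
})

test_that("injected effect sizes are recovered from projected deaths", {
  toy <- toy_inputs(mort_scale = 1, fert_level = 0)
  eff <- 0.6; af <- 0.5; dc <- 0.4
  fac <- 1 - eff * af * dc
  adj <- array(fac, c(3, 2, 1, 1))
  base <- project_cohorts(toy$pop0, toy$mort, toy$fert, toy$widths, years = 2016)
  scen <- project_cohorts(toy$pop0, toy$mort, toy$fert, toy$widths,
                          years = 2016, adjust = adj)
  for (b in 1:3) for (s in 1:2) {
    P <- toy$pop0[b, s]
    m_f <- -log(1 - base$deaths[b, s, 1, 1] / P)
    m_s <- -log(1 - scen$deaths[b, s, 1, 1] / P)
    expect_equal(1 - m_s / m_f, eff * af * dc, tolerance = 1e-6)
  }
})
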