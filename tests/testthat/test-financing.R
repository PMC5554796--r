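fx <- worked_fixture()
pop15 <- setNames(rep(1e6, 15), projection_years())

test_that("GDP compounds and zero growth with constant shares yields zero space", {
  p <- fx$profiles[[1]]
  p$gdp_growth <- rep(0.02, 15)
  fin <- project_financing(p, financing_scenario("moderate"), pop15)
  expect_equal(fin$gdp_pc[15], p$gdp_per_capita_2015 * 1.02^15, tolerance = 1e-12)
  p0 <- p
  p0$gdp_growth <- rep(0, 15)
  fin0 <- project_financing(p0, financing_scenario("moderate"), pop15)
  expect_equal(max(abs(fin0$available_incremental)), 0, tolerance = 1e-9)
  expect_true(all(fin$gghe_pc <= fin$the_pc + 1e-9))
})

test_that("optimistic financing dominates moderate on synthetic profiles", {
  cfg <- generator_config(seed = 21)
  cat_s <- generate_interventions(cfg, seed = 21)
  for (i in 1:10) {
    typ <- sample(typologies(), 1)
    inc <- sample(income_groups(), 1)
    p <- generate_country(cfg, typ, inc, cat_s, seed = 100 + i)
    opt <- project_financing(p, financing_scenario("optimistic"), pop15)
    mod <- project_financing(p, financing_scenario("moderate"), pop15)
    expect_true(all(opt$available_incremental >= mod$available_incremental - 1e-9))
  }
})

test_that("the gap is the positive part of cost minus space, and is anti-monotone", {
  fin <- tibble::tibble(year = projection_years(),
                        available_incremental = rep(6, 15))
  cost <- tibble::tibble(year = projection_years(), amount = rep(10, 15))
  g <- financing_gap(cost, fin)
  expect_equal(g$gap, rep(4, 15))
  cheap <- cost; cheap$amount <- rep(5, 15)
  expect_equal(financing_gap(cheap, fin)$gap, rep(0, 15))
  set.seed(3)
  for (i in 1:20) {
    fin$available_incremental <- runif(15, -5, 15)
    cost$amount <- runif(15, 0, 12)
    g1 <- financing_gap(cost, fin)
    expect_equal(g1$gap, pmax(0, cost$amount - fin$available_incremental))
    # more financing never increases the gap
    fin2 <- fin; fin2$available_incremental <- fin$available_incremental + runif(15, 0, 3)
    expect_true(all(financing_gap(cost, fin2)$gap <= g1$gap + 1e-12))
    # a high-efficiency cost stream never widens the gap
    eff <- cost; eff$amount <- cost$amount * 0.9
    expect_true(all(financing_gap(eff, fin)$gap <= g1$gap + 1e-12))
  }
})

test_that("gap summary averages over gap years only and ignores ordering", {
  gaps_bn <- c(0, 4, 6, 0, 0) * 1e9
  d <- tibble::tibble(country_id = "A", group = "g1", year = 2026:2030,
                      gap = gaps_bn, population = c(10, 12, 14, 16, 18) * 1e6)
  s <- gap_summary(d)
  expect_equal(s$n_countries_with_gap, 1)
  expect_equal(s$mean_annual_gap, 5)            # mean of 4 and 6 billion
  expect_equal(s$mean_population_during_gap_years, mean(c(12, 14)))
  # no gap anywhere: n = 0 and zeros
  none <- d; none$gap <- 0
  s0 <- gap_summary(none)
  expect_equal(s0$n_countries_with_gap, 0)
  expect_equal(s0$mean_annual_gap, 0)
  # ten synthetic countries against a per-country loop oracle
  set.seed(8)
  big <- purrr::map_dfr(1:10, function(i) tibble::tibble(
    country_id = paste0("C", i), group = sample(c("g1", "g2"), 1),
    year = 2026:2030, gap = pmax(0, rnorm(5, 1e9, 2e9)),
    population = runif(5, 1e6, 5e7)))
  s1 <- gap_summary(big)
  oracle <- big %>% dplyr::group_by(group, country_id) %>%
    dplyr::summarise(mg = if (any(gap > 0)) mean(gap[gap > 0]) else NA,
                     mp = if (any(gap > 0)) mean(population[gap > 0]) else NA,
                     .groups = "drop") %>%
    dplyr::group_by(group) %>%
    dplyr::summarise(n = sum(!is.na(mg)),
                     pop = sum(mp, na.rm = TRUE) / 1e6,
                     g = sum(mg, na.rm = TRUE) / 1e9)
  expect_equal(s1$n_countries_with_gap, oracle$n)
  expect_equal(s1$mean_annual_gap, oracle$g, tolerance = 1e-12)
  expect_equal(s1$mean_population_during_gap_years, oracle$pop, tolerance = 1e-12)
  shuffled <- big[sample(nrow(big)), ]
  expect_equal(gap_summary(shuffled), s1)
})
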