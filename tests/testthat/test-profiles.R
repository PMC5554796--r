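test_that("well-formed fixture profiles validate cleanly", {
  fx <- worked_fixture()
  expect_length(fx$profiles, 2)
  for (p in fx$profiles) expect_identical(validate_profile(p), character(0))
  expect_identical(validate_catalogue(fx$catalogue), character(0))
})

test_that("violations are returned, named by field, not raised", {
  p <- worked_fixture()$profiles[[1]]
  p$gghe_per_capita_2014 <- p$the_per_capita_2014 + 1
  v <- validate_profile(p)
  expect_length(v, 1)
  expect_match(v, "gghe_per_capita_2014")

  p2 <- worked_fixture()$profiles[[1]]
  p2$mortality_base["40-44", "male", "tuberculosis"] <- -0.01
  v2 <- validate_profile(p2)
  expect_length(v2, 1)
  expect_match(v2, "mortality_base")
  expect_match(v2, "tuberculosis")
  expect_match(v2, "40-44")

  p3 <- worked_fixture()$profiles[[1]]
  p3$baseline_coverage[["ncd_htn"]] <- 1.2
  expect_match(validate_profile(p3), "ncd_htn")
})

test_that("profile write/read round-trips losslessly (JSON and CSV bundle)", {
  fx <- worked_fixture()
  fields <- setdiff(names(fx$profiles[[1]]), character(0))
  for (fmt in c("json", "bundle")) {
    path <- if (fmt == "json") withr::local_tempfile(fileext = ".json")
            else withr::local_tempdir()
    write_profiles(fx$profiles, path)
    back <- read_profiles(path)
    expect_length(back, 2)  # row count preserved
    for (i in 1:2) {
      for (f in fields) {
        expect_equal(back[[i]][[f]], fx$profiles[[i]][[f]], tolerance = 1e-12,
                     label = sprintf("%s/%s/%s", fmt, i, f))
      }
    }
  }
})

test_that("schema and parse errors name the column and row", {
  fx <- worked_fixture()
  dir <- withr::local_tempdir()
  write_profiles(fx$profiles, dir)
  prof <- readr::read_csv(file.path(dir, "profiles.csv"), show_col_types = FALSE)
  readr::write_csv(prof[setdiff(names(prof), "gdp_per_capita_2015")],
                   file.path(dir, "profiles.csv"))
  expect_error(read_profiles(dir), "gdp_per_capita_2015")

  dir2 <- withr::local_tempdir()
  write_profiles(fx$profiles, dir2)
  cov <- readr::read_csv(file.path(dir2, "coverage.csv"), show_col_types = FALSE)
  cov$coverage <- as.character(cov$coverage)
  cov$coverage[2] <- "oops"
  readr::write_csv(cov, file.path(dir2, "coverage.csv"))
  expect_error(read_profiles(dir2), "row 2")

  p <- fx$profiles[[1]]
  p$baseline_coverage[["measles_vacc"]] <- 1.2
  f <- withr::local_tempfile(fileext = ".json")
  write_profiles(list(p), f)
  expect_error(read_profiles(f), "measles_vacc")
})

test_that("typology classification is total, matches the decision table, and is monotone", {
  th <- typology_thresholds(fragility_cutoff = 0.6,
                            capacity_cutpoints = c(0.35, 0.65))
  set.seed(11)
  for (i in 1:100) {
    ind <- list(active_conflict = runif(1) < 0.2,
                fragility_score = runif(1, 0, 1.2),
                system_capacity_score = runif(1))
    got <- classify_typology(ind, th)
    expect_identical(got, oracle_typology(ind$active_conflict,
                                          ind$fragility_score,
                                          ind$system_capacity_score,
                                          0.6, 0.35, 0.65))
    expect_true(got %in% typologies())
  }
  # boundary values go to the higher-capacity class
  mk <- function(s) classify_typology(list(active_conflict = FALSE,
                                           fragility_score = 0,
                                           system_capacity_score = s), th)
  expect_identical(mk(0.35), "hs2")
  expect_identical(mk(0.65), "hs3")
  expect_identical(mk(1.0), "hs3")
  expect_identical(classify_typology(list(active_conflict = TRUE,
                                          fragility_score = 0,
                                          system_capacity_score = 1), th),
                   "conflict")
  # monotone: increasing capacity never lowers the hs category
  lvl <- c(hs1 = 1, hs2 = 2, hs3 = 3)
  ss <- seq(0, 1, by = 0.01)
  ks <- lvl[vapply(ss, mk, character(1))]
  expect_true(all(diff(ks) >= 0))
  expect_error(classify_typology(list(active_conflict = FALSE,
                                      fragility_score = 0,
                                      system_capacity_score = 0.5),
                                 list(fragility_cutoff = 0.5,
                                      capacity_cutpoints = c(0.7, 0.3))),
               "c1 < c2")
})
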