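# Profile serialisation: a single JSON file, or a CSV bundle (one scalars
# table plus long-format companions for the age/cause arrays).

profile_to_list <- function(p) {
  list(
    country_id = p$country_id,
    income_group = p$income_group,
    typology = p$typology,
    population_base = mat_to_long(p$population_base, "count"),
    fertility_rate = as.list(p$fertility_rate),
    mortality_base = arr_to_long(p$mortality_base, "rate"),
    stillbirth_rate = p$stillbirth_rate,
    baseline_coverage = as.list(p$baseline_coverage),
    workforce_density_base = as.list(p$workforce_density_base),
    facility_density_base = as.list(p$facility_density_base),
    gdp_per_capita_2015 = p$gdp_per_capita_2015,
    gdp_growth = p$gdp_growth,
    govt_revenue_share = p$govt_revenue_share,
    health_share_of_govt = p$health_share_of_govt,
    the_per_capita_2014 = p$the_per_capita_2014,
    gghe_per_capita_2014 = p$gghe_per_capita_2014
  )
}

mat_to_long <- function(m, value_name) {
  d <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(d) <- c("band", "sex", value_name)
  d
}

arr_to_long <- function(a, value_name) {
  d <- as.data.frame.table(a, stringsAsFactors = FALSE)
  names(d) <- c("band", "sex", "cause", value_name)
  d
}

long_to_mat <- function(d, value_name) {
  m <- matrix(0, nrow = 19, ncol = 2,
              dimnames = list(age_bands()$band, sexes()))
  m[cbind(d$band, d$sex)] <- d[[value_name]]
  m
}

long_to_arr <- function(d, value_name) {
  causes <- unique(d$cause)
  a <- array(0, dim = c(19, 2, length(causes)),
             dimnames = list(age_bands()$band, sexes(), causes))
  a[cbind(d$band, d$sex, d$cause)] <- d[[value_name]]
  a
}

profile_from_list <- function(x) {
  country_profile(
    country_id = x$country_id,
    income_group = x$income_group,
    typology = x$typology,
    population_base = long_to_mat(as.data.frame(x$population_base), "count"),
    fertility_rate = unlist(x$fertility_rate)[fertility_bands()],
    mortality_base = long_to_arr(as.data.frame(x$mortality_base), "rate"),
    stillbirth_rate = x$stillbirth_rate,
    baseline_coverage = unlist(x$baseline_coverage),
    workforce_density_base = unlist(x$workforce_density_base)[c("doctor", "nurse_midwife", "other")],
    facility_density_base = unlist(x$facility_density_base)[c("primary", "hospital")],
    gdp_per_capita_2015 = x$gdp_per_capita_2015,
    gdp_growth = unlist(x$gdp_growth),
    govt_revenue_share = x$govt_revenue_share,
    health_share_of_govt = x$health_share_of_govt,
    the_per_capita_2014 = x$the_per_capita_2014,
    gghe_per_capita_2014 = x$gghe_per_capita_2014
  )
}

#' Write country profiles
#'
#' Writes a list of profiles either to a single JSON file (`path` ending in
#' `.json`; lossless at full double precision) or to a CSV bundle directory
#' (`profiles.csv` with one row of scalars per country plus long-format
#' `population.csv`, `mortality.csv`, `fertility.csv`, `coverage.csv`,
#' `growth.csv` companions).
#'
#' @param profiles List of [country_profile()] objects.
#' @param path Output `.json` file or directory.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "country_profile")) profiles <- list(profiles)
  if (grepl("\\.json$", path)) {
    lst <- lapply(profiles, profile_to_list)
    names(lst) <- vapply(profiles, function(p) p$country_id, character(1))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scal <- purrr::map_dfr(profiles, function(p) tibble::tibble(
    country_id = p$country_id, income_group = p$income_group,
    typology = p$typology, stillbirth_rate = p$stillbirth_rate,
    wd_doctor = p$workforce_density_base[["doctor"]],
    wd_nurse_midwife = p$workforce_density_base[["nurse_midwife"]],
    wd_other = p$workforce_density_base[["other"]],
    fd_primary = p$facility_density_base[["primary"]],
    fd_hospital = p$facility_density_base[["hospital"]],
    gdp_per_capita_2015 = p$gdp_per_capita_2015,
    govt_revenue_share = p$govt_revenue_share,
    health_share_of_govt = p$health_share_of_govt,
    the_per_capita_2014 = p$the_per_capita_2014,
    gghe_per_capita_2014 = p$gghe_per_capita_2014))
  readr::write_csv(scal, file.path(path, "profiles.csv"))
  long <- function(fn) purrr::map_dfr(profiles, fn)
  readr::write_csv(long(function(p)
    cbind(country_id = p$country_id, mat_to_long(p$population_base, "count"))),
    file.path(path, "population.csv"))
  readr::write_csv(long(function(p)
    cbind(country_id = p$country_id, arr_to_long(p$mortality_base, "rate"))),
    file.path(path, "mortality.csv"))
  readr::write_csv(long(function(p) tibble::tibble(
    country_id = p$country_id, band = names(p$fertility_rate),
    rate = unname(p$fertility_rate))), file.path(path, "fertility.csv"))
  readr::write_csv(long(function(p) tibble::tibble(
    country_id = p$country_id, intervention_id = names(p$baseline_coverage),
    coverage = unname(p$baseline_coverage))), file.path(path, "coverage.csv"))
  readr::write_csv(long(function(p) tibble::tibble(
    country_id = p$country_id, year = 2016:2030, growth = p$gdp_growth)),
    file.path(path, "growth.csv"))
  invisible(path)
}

require_columns <- function(d, cols, file) {
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop(sprintf("schema error in %s: missing mandatory column(s) %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(d)
}

check_numeric <- function(d, cols, file) {
  for (cl in cols) {
    x <- d[[cl]]
    if (is.character(x)) {
      num <- suppressWarnings(as.numeric(x))
      if (anyNA(num) && !anyNA(x))
        stop(sprintf("parse error in %s: non-numeric value in column %s at row %d",
                     file, cl, which(is.na(num))[1]), call. = FALSE)
      d[[cl]] <- num
    }
    if (anyNA(d[[cl]]))
      stop(sprintf("parse error in %s: missing value in column %s at row %d",
                   file, cl, which(is.na(d[[cl]]))[1]), call. = FALSE)
  }
  d
}

#' Read country profiles
#'
#' Reads profiles from a JSON file or a CSV bundle directory written by
#' [write_profiles()].  Every returned profile is checked with
#' [validate_profile()]; any violation aborts the read.
#'
#' @param path A `.json` file or a bundle directory.
#' @return List of validated [country_profile()] objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  profiles <- if (grepl("\\.json$", path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
    if (!is.null(raw$country_id)) raw <- list(raw)  # single profile
    lapply(raw, profile_from_list)
  } else {
    read_profile_bundle(path)
  }
  for (p in profiles) {
    bad <- validate_profile(p)
    if (length(bad))
      stop(sprintf("profile %s failed validation: %s", p$country_id,
                   paste(bad, collapse = "; ")), call. = FALSE)
  }
  profiles
}

read_profile_bundle <- function(path) {
  rd <- function(f, cols, num_cols) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("missing bundle file: ", fp, call. = FALSE)
    d <- readr::read_csv(fp, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
    d <- require_columns(d, cols, f)
    check_numeric(as.data.frame(d), num_cols, f)
  }
  scal_num <- c("stillbirth_rate", "wd_doctor", "wd_nurse_midwife", "wd_other",
                "fd_primary", "fd_hospital", "gdp_per_capita_2015",
                "govt_revenue_share", "health_share_of_govt",
                "the_per_capita_2014", "gghe_per_capita_2014")
  scal <- rd("profiles.csv", c("country_id", "income_group", "typology", scal_num), scal_num)
  pop <- rd("population.csv", c("country_id", "band", "sex", "count"), "count")
  mort <- rd("mortality.csv", c("country_id", "band", "sex", "cause", "rate"), "rate")
  fert <- rd("fertility.csv", c("country_id", "band", "rate"), "rate")
  cov <- rd("coverage.csv", c("country_id", "intervention_id", "coverage"), "coverage")
  gro <- rd("growth.csv", c("country_id", "year", "growth"), c("year", "growth"))

  lapply(seq_len(nrow(scal)), function(i) {
    id <- scal$country_id[i]
    fi <- fert[fert$country_id == id, ]
    ci <- cov[cov$country_id == id, ]
    gi <- gro[gro$country_id == id, ]
    gi <- gi[order(gi$year), ]
    country_profile(
      country_id = id,
      income_group = scal$income_group[i], typology = scal$typology[i],
      population_base = long_to_mat(pop[pop$country_id == id, ], "count"),
      fertility_rate = setNames(fi$rate, fi$band)[fertility_bands()],
      mortality_base = long_to_arr(mort[mort$country_id == id, ], "rate"),
      stillbirth_rate = scal$stillbirth_rate[i],
      baseline_coverage = setNames(ci$coverage, ci$intervention_id),
      workforce_density_base = c(doctor = scal$wd_doctor[i],
                                 nurse_midwife = scal$wd_nurse_midwife[i],
                                 other = scal$wd_other[i]),
      facility_density_base = c(primary = scal$fd_primary[i],
                                hospital = scal$fd_hospital[i]),
      gdp_per_capita_2015 = scal$gdp_per_capita_2015[i],
      gdp_growth = gi$growth,
      govt_revenue_share = scal$govt_revenue_share[i],
      health_share_of_govt = scal$health_share_of_govt[i],
      the_per_capita_2014 = scal$the_per_capita_2014[i],
      gghe_per_capita_2014 = scal$gghe_per_capita_2014[i])
  })
}
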