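#' Construct a country profile
#'
#' A country profile bundles the demographic, epidemiological, baseline
#' service-delivery and macro-fiscal inputs the projection needs for one
#' country.  Monetary fields are constant 2014 US$.
#'
#' @param country_id Character identifier.
#' @param income_group One of `"low"`, `"lower_middle"`, `"upper_middle"`.
#' @param typology One of `"conflict"`, `"vulnerable"`, `"hs1"`, `"hs2"`,
#'   `"hs3"`; may be supplied directly or derived via [classify_typology()].
#' @param population_base Numeric matrix (19 age bands x 2 sexes, dimnames
#'   `age_bands()$band` x `sexes()`) of 2015 population counts.
#' @param fertility_rate Named numeric vector of births per woman-year over
#'   the seven maternal age bands ([fertility_bands()]).
#' @param mortality_base Numeric array `[band, sex, cause]` of deaths per
#'   person-year by cause; dimnames required.
#' @param stillbirth_rate Stillbirths per livebirth (pseudo-cause input).
#' @param baseline_coverage Named numeric vector in `[0,1]`, one entry per
#'   intervention id.
#' @param workforce_density_base Named vector (`doctor`, `nurse_midwife`,
#'   `other`), workers per 1000 population.
#' @param facility_density_base Named vector (`primary`, `hospital`),
#'   facilities per 10 000 population.
#' @param gdp_per_capita_2015 GDP per person, US$ 2014.
#' @param gdp_growth Annual real growth fraction; scalar or length-15 vector
#'   covering 2016-2030.
#' @param govt_revenue_share Government revenue as a fraction of GDP.
#' @param health_share_of_govt Health share of government spending.
#' @param the_per_capita_2014 Total health expenditure per person, US$ 2014.
#' @param gghe_per_capita_2014 General government health expenditure per
#'   person, US$ 2014 (must not exceed `the_per_capita_2014`).
#'
#' @return An object of class `country_profile`.
#' @seealso [validate_profile()], [read_profiles()], [generate_country()]
#' @export
country_profile <- function(country_id, income_group, typology,
                            population_base, fertility_rate, mortality_base,
                            stillbirth_rate = 0.018,
                            baseline_coverage,
                            workforce_density_base, facility_density_base,
                            gdp_per_capita_2015, gdp_growth,
                            govt_revenue_share, health_share_of_govt,
                            the_per_capita_2014, gghe_per_capita_2014) {
  if (length(gdp_growth) == 1L) gdp_growth <- rep(gdp_growth, 15L)
  structure(list(
    country_id = as.character(country_id),
    income_group = income_group,
    typology = typology,
    population_base = population_base,
    fertility_rate = fertility_rate,
    mortality_base = mortality_base,
    stillbirth_rate = stillbirth_rate,
    baseline_coverage = baseline_coverage,
    workforce_density_base = workforce_density_base,
    facility_density_base = facility_density_base,
    gdp_per_capita_2015 = gdp_per_capita_2015,
    gdp_growth = gdp_growth,
    govt_revenue_share = govt_revenue_share,
    health_share_of_govt = health_share_of_govt,
    the_per_capita_2014 = the_per_capita_2014,
    gghe_per_capita_2014 = gghe_per_capita_2014
  ), class = "country_profile")
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile %s: %s, %s, pop %.2fM, GDP/cap $%.0f>\n",
              x$country_id, x$income_group, x$typology,
              sum(x$population_base) / 1e6, x$gdp_per_capita_2015))
  invisible(x)
}

income_groups <- function() c("low", "lower_middle", "upper_middle")

#' @rdname classify_typology
#' @export
typologies <- function() c("conflict", "vulnerable", "hs1", "hs2", "hs3")

#' Validate a country profile
#'
#' Checks every structural invariant of a [country_profile()]: non-negative
#' rates and counts, coverage and shares in `[0,1]`, the documented 19-band
#' age structure, and government health expenditure not exceeding total
#' health expenditure.  Violations are returned, not raised, so callers can
#' report them all at once.
#'
#' @param profile A `country_profile`.
#' @return Character vector of violations (empty when the profile is valid);
#'   each entry names the offending field and rule.
#' @export
validate_profile <- function(profile) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  ab <- age_bands()

  p <- profile$population_base
  if (!is.matrix(p) || !identical(dim(p), c(19L, 2L)) ||
      !identical(rownames(p), ab$band) || !identical(colnames(p), sexes())) {
    add("population_base: must be a 19 x 2 matrix over age_bands() x sexes()")
  } else if (any(!is.finite(p)) || any(p < 0)) {
    bad <- which(!is.finite(p) | p < 0, arr.ind = TRUE)[1, ]
    add(sprintf("population_base: negative or non-finite count at [%s, %s]",
                rownames(p)[bad[1]], colnames(p)[bad[2]]))
  }

  f <- profile$fertility_rate
  if (!identical(names(f), fertility_bands())) {
    add("fertility_rate: must be named over the seven maternal age bands")
  } else if (any(!is.finite(f)) || any(f < 0)) {
    add(sprintf("fertility_rate: negative or non-finite rate in band %s",
                names(f)[which(!is.finite(f) | f < 0)[1]]))
  }

  m <- profile$mortality_base
  if (!is.array(m) || length(dim(m)) != 3L ||
      !identical(dimnames(m)[[1]], ab$band) ||
      !identical(dimnames(m)[[2]], sexes())) {
    add("mortality_base: must be an array [age band, sex, cause] with dimnames")
  } else if (any(!is.finite(m)) || any(m < 0)) {
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)[1, ]
    add(sprintf("mortality_base: negative or non-finite rate at cause %s, age %s, sex %s",
                dimnames(m)[[3]][bad[3]], dimnames(m)[[1]][bad[1]],
                dimnames(m)[[2]][bad[2]]))
  }

  if (!is.finite(profile$stillbirth_rate) || profile$stillbirth_rate < 0)
    add("stillbirth_rate: must be >= 0")

  cov <- profile$baseline_coverage
  if (is.null(names(cov)) || anyDuplicated(names(cov)))
    add("baseline_coverage: must be uniquely named by intervention_id")
  bad_cov <- which(!is.finite(cov) | cov < 0 | cov > 1)
  if (length(bad_cov))
    add(sprintf("baseline_coverage: value outside [0,1] for %s",
                names(cov)[bad_cov[1]]))

  wd <- profile$workforce_density_base
  if (!identical(sort(names(wd)), sort(c("doctor", "nurse_midwife", "other"))) ||
      any(!is.finite(wd)) || any(wd < 0))
    add("workforce_density_base: needs non-negative doctor/nurse_midwife/other densities")
  fd <- profile$facility_density_base
  if (!identical(sort(names(fd)), sort(c("hospital", "primary"))) ||
      any(!is.finite(fd)) || any(fd < 0))
    add("facility_density_base: needs non-negative primary/hospital densities")

  if (!profile$income_group %in% income_groups())
    add("income_group: must be low/lower_middle/upper_middle")
  if (!profile$typology %in% typologies())
    add("typology: must be one of conflict/vulnerable/hs1/hs2/hs3")

  if (!is.finite(profile$gdp_per_capita_2015) || profile$gdp_per_capita_2015 <= 0)
    add("gdp_per_capita_2015: must be > 0")
  if (length(profile$gdp_growth) != 15L || any(!is.finite(profile$gdp_growth)))
    add("gdp_growth: must be 15 finite annual fractions (2016-2030)")
  for (fld in c("govt_revenue_share", "health_share_of_govt")) {
    x <- profile[[fld]]
    if (!is.finite(x) || x < 0 || x > 1)
      add(sprintf("%s: must lie in [0,1]", fld))
  }
  for (fld in c("the_per_capita_2014", "gghe_per_capita_2014")) {
    x <- profile[[fld]]
    if (!is.finite(x) || x < 0) add(sprintf("%s: must be >= 0", fld))
  }
  if (is.finite(profile$gghe_per_capita_2014) && is.finite(profile$the_per_capita_2014) &&
      profile$gghe_per_capita_2014 > profile$the_per_capita_2014)
    add("gghe_per_capita_2014: government health expenditure exceeds total health expenditure")

  v
}

#' Typology classification thresholds
#'
#' @param fragility_cutoff Countries with `fragility_score` at or above this
#'   value (and no active conflict) are classed `vulnerable`.
#' @param capacity_cutpoints Two increasing cutpoints `(c1, c2)` partitioning
#'   the system-capacity score into hs1 / hs2 / hs3.
#' @return A list usable as the `thresholds` argument of [classify_typology()].
#' @export
typology_thresholds <- function(fragility_cutoff = 0.6,
                                capacity_cutpoints = c(0.35, 0.65)) {
  if (length(capacity_cutpoints) != 2L ||
      !(capacity_cutpoints[1] < capacity_cutpoints[2]))
    stop("capacity_cutpoints must be two increasing values (c1 < c2)", call. = FALSE)
  list(fragility_cutoff = fragility_cutoff,
       capacity_cutpoints = capacity_cutpoints)
}

#' Classify a country into one of five health-system typologies
#'
#' Countries are grouped into conflict-affected, vulnerable-systems, and
#' health-system categories 1-3, which downstream gate the assumed absorptive
#' capacity (maximum annual coverage increments for clinical platforms).
#' Active conflict dominates; otherwise high fragility marks a vulnerable
#' system; otherwise the system-capacity score (a `[0,1]` composite of
#' workforce density and service-delivery performance) is partitioned by two
#' cutpoints.  Scores exactly at a cutpoint are assigned to the
#' higher-capacity class.
#'
#' @param ind List with `active_conflict` (logical), `fragility_score`
#'   (>= 0) and `system_capacity_score` (in `[0,1]`).
#' @param thresholds See [typology_thresholds()].
#' @return One of `"conflict"`, `"vulnerable"`, `"hs1"`, `"hs2"`, `"hs3"`.
#' @export
#' @examples
#' classify_typology(list(active_conflict = FALSE, fragility_score = 0.1,
#'                        system_capacity_score = 0.9))
classify_typology <- function(ind, thresholds = typology_thresholds()) {
  cp <- thresholds$capacity_cutpoints
  if (length(cp) != 2L || !(cp[1] < cp[2]))
    stop("capacity cutpoints must satisfy c1 < c2", call. = FALSE)
  stopifnot(is.finite(ind$fragility_score), ind$fragility_score >= 0,
            is.finite(ind$system_capacity_score),
            ind$system_capacity_score >= 0, ind$system_capacity_score <= 1)
  if (isTRUE(ind$active_conflict)) return("conflict")
  if (ind$fragility_score >= thresholds$fragility_cutoff) return("vulnerable")
  s <- ind$system_capacity_score
  if (s >= cp[2]) "hs3" else if (s >= cp[1]) "hs2" else "hs1"
}
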