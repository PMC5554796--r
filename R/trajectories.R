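#' Scale-up scenario specification
#'
#' Defines how coverage expands from its 2015 baseline: the global target
#' level, the fraction of the coverage gap a scenario aims to close, the
#' attainment year, ramp shapes per platform, and the absorptive-capacity
#' caps (maximum coverage increase per year, as a fraction) per platform and
#' typology.  The `flatline` scenario is the counterfactual that holds 2015
#' coverage constant through 2030.
#'
#' Policy/population-wide and periodic outreach services ramp linearly and
#' are assumed fast to scale in every setting (default caps of 1 never
#' bind); clinical services follow a logistic ramp clipped at the
#' typology-specific cap, so weaker systems diverge from the target.  The
#' progress scenario closes a configurable fraction (default 80%) of the gap
#' the ambitious scenario closes.
#'
#' @param name `"progress"`, `"ambitious"` or `"flatline"`.
#' @param global_target Default global coverage target before frontier caps.
#' @param gap_fraction Fraction of the baseline-to-target gap closed
#'   (ambitious 1, progress 0.8, flatline 0).
#' @param target_attainment_year Year by which unconstrained ramps reach the
#'   target.
#' @param max_annual_increment 4 x 5 matrix (platform x typology) of maximum
#'   annual coverage increments.
#' @param ramp_shape Named character vector per platform, `"linear"` or
#'   `"logistic"`.
#' @param logistic_steepness Steepness of the normalised logistic ramp.
#' @param benchmark_ambition Fraction of the input-density gap (workforce,
#'   facilities) closed by the attainment year.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("ambitious", "progress", "flatline"),
                          global_target = 0.95,
                          gap_fraction = NULL,
                          target_attainment_year = 2030,
                          max_annual_increment = default_increment_caps(),
                          ramp_shape = c(policy_population_wide = "linear",
                                         periodic_outreach = "linear",
                                         first_level_clinical = "logistic",
                                         specialised_clinical = "logistic"),
                          logistic_steepness = 8,
                          benchmark_ambition = NULL) {
  name <- match.arg(name)
  if (is.null(gap_fraction))
    gap_fraction <- switch(name, ambitious = 1, progress = 0.8, flatline = 0)
  if (is.null(benchmark_ambition))
    benchmark_ambition <- switch(name, ambitious = 1, progress = 0.8, flatline = 0)
  if (name != "flatline" && any(max_annual_increment <= 0))
    stop("max_annual_increment must be > 0 for non-flatline scenarios", call. = FALSE)
  if (target_attainment_year < 2016 || target_attainment_year > 2030)
    stop("target_attainment_year must lie in [2016, 2030]", call. = FALSE)
  structure(list(name = name, global_target = global_target,
                 gap_fraction = gap_fraction,
                 target_attainment_year = target_attainment_year,
                 max_annual_increment = max_annual_increment,
                 ramp_shape = ramp_shape,
                 logistic_steepness = logistic_steepness,
                 benchmark_ambition = benchmark_ambition),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
default_increment_caps <- function() {
  caps <- rbind(
    policy_population_wide = c(1, 1, 1, 1, 1),
    periodic_outreach      = c(1, 1, 1, 1, 1),
    first_level_clinical   = c(0.02, 0.03, 0.04, 0.05, 0.06),
    specialised_clinical   = c(0.01, 0.02, 0.03, 0.04, 0.05))
  colnames(caps) <- typologies()
  caps
}

#' Projection years
#' @return Integer vector 2016:2030.
#' @export
projection_years <- function() 2016:2030

#' Target coverage for an intervention under a scenario
#'
#' The attainable target is the global target clipped at the intervention's
#' frontier cap (e.g. 0.60 for management of non-communicable diseases, 0.95
#' for immunisation), never below the current baseline (coverage is never
#' reduced).  The progress scenario closes `gap_fraction` of the
#' baseline-to-ambitious-target gap, so progress targets never exceed
#' ambitious ones.
#'
#' @param interv One catalogue row (or list with `frontier_cap`).
#' @param profile A [country_profile()] (supplies the baseline coverage).
#' @param scenario A [scenario_spec()]; must not be flatline.
#' @return Target coverage fraction.
#' @export
target_coverage <- function(interv, profile, scenario) {
  if (scenario$name == "flatline")
    stop("flatline has no scale-up target; use flatline()", call. = FALSE)
  cap <- interv$frontier_cap
  if (!is.finite(cap) || cap < 0 || cap > 1)
    stop("frontier cap outside [0,1] for ", interv$intervention_id, call. = FALSE)
  baseline <- unname(profile$baseline_coverage[[interv$intervention_id]])
  full <- max(baseline, min(scenario$global_target, cap))
  baseline + scenario$gap_fraction * (full - baseline)
}

norm_logistic <- function(u, k) {
  f <- function(x) 1 / (1 + exp(-k * (x - 0.5)))
  (f(u) - f(0)) / (f(1) - f(0))
}

#' Build an annual coverage trajectory
#'
#' Produces the 2016-2030 coverage path from `baseline` to `target`.  The
#' unconstrained path follows the platform's ramp shape (linear or
#' normalised logistic), reaching the target at the scenario's attainment
#' year.  Each annual step is clipped at the platform x typology
#' absorptive-capacity cap; when the cap binds, the path rises at the full
#' cap (catch-up towards the shape and target is permitted), so under a
#' tight cap the path is `baseline + cumulative min(cap, remaining gap)` and
#' the final value is the capped maximum rather than the target.
#'
#' @param baseline Baseline (2015) coverage fraction.
#' @param target Target coverage (apply [target_coverage()] first).
#' @param platform One of [platforms()].
#' @param typology One of [typologies()].
#' @param scenario A [scenario_spec()].
#' @return Named numeric vector of 15 coverage values (2016-2030).
#' @export
build_trajectory <- function(baseline, target, platform, typology, scenario) {
  if (baseline > target + 1e-12)
    stop("baseline exceeds target; apply target_coverage() first", call. = FALSE)
  years <- projection_years()
  n <- length(years)
  span <- max(1L, scenario$target_attainment_year - 2016L)
  u <- pmin(1, (years - 2016L) / span)
  shape <- if (scenario$ramp_shape[[platform]] == "logistic")
    norm_logistic(u, scenario$logistic_steepness) else u
  path_unc <- baseline + (target - baseline) * shape
  cap <- scenario$max_annual_increment[platform, typology]
  v <- numeric(n)
  prev <- baseline
  for (i in seq_len(n)) {
    step <- min(cap, max(path_unc[i] - prev, 0), target - prev)
    v[i] <- prev + step
    prev <- v[i]
  }
  setNames(v, years)
}

#' Flatline counterfactual coverage path
#'
#' @param baseline Baseline coverage fraction in `[0,1]`.
#' @return Named numeric vector holding the baseline constant over 2016-2030.
#' @export
flatline <- function(baseline) {
  stopifnot(baseline >= 0, baseline <= 1)
  setNames(rep(baseline, length(projection_years())), projection_years())
}

#' Coverage paths for a whole catalogue
#'
#' @param profile A validated [country_profile()].
#' @param catalogue Intervention catalogue tibble.
#' @param scenario A [scenario_spec()] (use `scenario_spec("flatline")` for
#'   the counterfactual).
#' @return Numeric matrix interventions x years (rownames intervention_id,
#'   colnames 2016-2030).
#' @export
build_coverage_paths <- function(profile, catalogue, scenario) {
  years <- projection_years()
  out <- matrix(NA_real_, nrow(catalogue), length(years),
                dimnames = list(catalogue$intervention_id, years))
  for (i in seq_len(nrow(catalogue))) {
    id <- catalogue$intervention_id[i]
    base <- unname(profile$baseline_coverage[[id]])
    out[i, ] <- if (scenario$name == "flatline") flatline(base)
    else build_trajectory(base,
                          target_coverage(catalogue[i, ], profile, scenario),
                          catalogue$platform[i], profile$typology, scenario)
  }
  out
}

#' Export coverage paths as a long tibble
#'
#' @param paths Matrix from [build_coverage_paths()].
#' @param country_id Country identifier to attach.
#' @return Tibble (country_id, intervention_id, year, coverage).
#' @export
coverage_long <- function(paths, country_id) {
  d <- as.data.frame.table(paths, stringsAsFactors = FALSE)
  names(d) <- c("intervention_id", "year", "coverage")
  tibble::tibble(country_id = country_id,
                 intervention_id = d$intervention_id,
                 year = as.integer(d$year), coverage = d$coverage)
}
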