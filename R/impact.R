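#' Adjust a mortality rate for scaled-up intervention coverage
#'
#' The impact model is a multiplicative residual abstraction: each
#' intervention reaching a cause multiplies the cause-specific rate by
#' `1 - effectiveness * affected_fraction * delta_coverage`.  Stacking is a
#' product, hence order-independent, and the adjusted rate stays in
#' `(0, m]` for factors in `[0,1]`.
#'
#' @param base_rate Baseline rate (deaths per person-year).
#' @param effectiveness Vector of proportional reductions at full coverage.
#' @param affected_fraction Vector of fractions of cause deaths in scope.
#' @param coverage_delta Vector of coverage increases over baseline.
#' @return The adjusted rate.
#' @export
#' @examples
#' adjusted_mortality(0.01, 0.5, 1, 0.4)  # 0.008
adjusted_mortality <- function(base_rate, effectiveness, affected_fraction,
                               coverage_delta) {
  chk <- function(x, nm) {
    if (any(!is.finite(x) | x < 0 | x > 1))
      stop(nm, " must lie in [0,1]", call. = FALSE)
  }
  chk(effectiveness, "effectiveness")
  chk(affected_fraction, "affected_fraction")
  chk(coverage_delta, "coverage_delta")
  base_rate * prod(1 - effectiveness * affected_fraction * coverage_delta)
}

#' Cohort-component population projection (engine)
#'
#' Advances a population on an arbitrary abridged band structure one year at
#' a time: cause-specific hazards are summed, survival applied as
#' `exp(-M)`, a fraction `1/width` of each band's survivors advances to the
#' next band (the open band retains everyone), and births (fertility applied
#' to start-of-year female population, split by the sex ratio at birth) enter
#' the first band.  No migration.  Stillbirths are tracked as a pseudo-cause
#' proportional to livebirths.
#'
#' @param pop0 Start population: matrix bands x 2 (`female`, `male`).
#' @param mortality Array bands x 2 x causes of baseline rates.
#' @param fertility Births per woman-year, full-length vector over bands
#'   (zero outside reproductive ages); `NULL` for none.
#' @param widths Band widths in years (`Inf` for the open band).
#' @param years Calendar years to project (population is recorded at the
#'   start of each).
#' @param adjust Optional array bands x 2 x causes x years of multiplicative
#'   rate adjustments (defaults to 1).
#' @param srb Sex ratio at birth (male:female), default 1.05.
#' @param stillbirth_rate Stillbirths per livebirth.
#' @param stillbirth_adjust Optional per-year multiplier on the stillbirth
#'   rate (coverage effects on the stillbirth pseudo-cause).
#' @return List of class `population_projection`: `population`
#'   (bands x 2 x years, start-of-year), `deaths`
#'   (bands x 2 x causes x years), `hazard` (bands x 2 x years, all-cause),
#'   `births`, `stillbirths` (per year), `widths`, `years`.
#' @export
project_cohorts <- function(pop0, mortality, fertility = NULL,
                            widths = age_bands()$width,
                            years = projection_years(),
                            adjust = NULL, srb = 1.05,
                            stillbirth_rate = 0, stillbirth_adjust = NULL) {
  nb <- nrow(pop0); ny <- length(years)
  nc <- dim(mortality)[3]
  cause_names <- dimnames(mortality)[[3]]
  if (is.null(cause_names)) cause_names <- paste0("cause", seq_len(nc))
  if (is.null(fertility)) fertility <- numeric(nb)
  if (is.null(stillbirth_adjust)) stillbirth_adjust <- rep(1, ny)
  pop_arr <- array(0, c(nb, 2, ny),
                   dimnames = list(rownames(pop0), sexes(), years))
  death_arr <- array(0, c(nb, 2, nc, ny),
                     dimnames = list(rownames(pop0), sexes(), cause_names, years))
  haz_arr <- array(0, c(nb, 2, ny),
                   dimnames = list(rownames(pop0), sexes(), years))
  births <- stillbirths <- setNames(numeric(ny), years)
  pop <- pop0
  male_frac <- srb / (1 + srb)
  adv <- 1 / widths  # fraction advancing each year; 0 for the open band
  for (t in seq_len(ny)) {
    m_t <- if (is.null(adjust)) mortality else {
      a_t <- adjust[, , , t, drop = FALSE]
      dim(a_t) <- dim(mortality)
      mortality * a_t
    }
    M <- apply(m_t, c(1, 2), sum)
    q <- -expm1(-M)
    deaths_tot <- pop * q
    share <- array(0, dim(m_t))
    pos <- M > 0
    for (k in seq_len(nc)) {
      sh <- m_t[, , k] ; sh[pos] <- sh[pos] / M[pos]; sh[!pos] <- 0
      death_arr[, , k, t] <- deaths_tot * sh
    }
    b <- sum(fertility * pop[, "female"])
    births[t] <- b
    stillbirths[t] <- b * stillbirth_rate * stillbirth_adjust[t]
    pop_arr[, , t] <- pop
    haz_arr[, , t] <- M
    surv <- pop - deaths_tot
    out <- surv * adv
    nxt <- surv - out
    if (nb > 1) nxt[2:nb, ] <- nxt[2:nb, ] + out[1:(nb - 1), ]
    nxt[1, ] <- nxt[1, ] + b * c(1 - male_frac, male_frac)
    pop <- nxt
  }
  structure(list(population = pop_arr, deaths = death_arr, hazard = haz_arr,
                 births = births, stillbirths = stillbirths,
                 widths = widths, years = years),
            class = "population_projection")
}

# multiplicative hazard adjustment array implied by a coverage matrix
mortality_adjustment <- function(profile, catalogue, coverage) {
  years <- projection_years(); ny <- length(years)
  mb <- profile$mortality_base
  adj <- array(1, c(dim(mb), ny),
               dimnames = c(dimnames(mb), list(years)))
  sb_adj <- rep(1, ny)
  ab <- age_bands()
  for (i in seq_len(nrow(catalogue))) {
    ef <- catalogue$effects[[i]]
    if (!nrow(ef)) next
    id <- catalogue$intervention_id[i]
    dcov <- pmax(0, coverage[id, ] - unname(profile$baseline_coverage[[id]]))
    for (j in seq_len(nrow(ef))) {
      fac <- 1 - ef$effectiveness[j] * ef$affected_fraction[j] * dcov
      if (ef$cause[j] == "stillbirth") {
        sb_adj <- sb_adj * fac
        next
      }
      bsel <- ab$band[ab$start >= ef$age_lo[j] & ab$start <= ef$age_hi[j]]
      ssel <- if (ef$sex[j] == "both") sexes() else ef$sex[j]
      for (t in seq_len(ny))
        adj[bsel, ssel, ef$cause[j], t] <- adj[bsel, ssel, ef$cause[j], t] * fac[t]
    }
  }
  list(adjust = adj, stillbirth_adjust = sb_adj)
}

#' Project a country's population under a coverage scenario
#'
#' Wraps [project_cohorts()] for a [country_profile()]: coverage increases
#' over baseline reduce cause-specific mortality via the multiplicative
#' residual model, need is therefore dynamic (averted deaths enlarge future
#' cohorts and future population in need).
#'
#' @param profile Validated [country_profile()].
#' @param catalogue Intervention catalogue.
#' @param coverage Coverage matrix from [build_coverage_paths()].
#' @param srb Sex ratio at birth.
#' @return A `population_projection` (see [project_cohorts()]).
#' @export
project_population <- function(profile, catalogue, coverage, srb = 1.05) {
  fert <- numeric(19)
  names(fert) <- age_bands()$band
  fert[names(profile$fertility_rate)] <- profile$fertility_rate
  adj <- mortality_adjustment(profile, catalogue, coverage)
  project_cohorts(profile$population_base, profile$mortality_base,
                  fertility = fert, adjust = adj$adjust, srb = srb,
                  stillbirth_rate = profile$stillbirth_rate,
                  stillbirth_adjust = adj$stillbirth_adjust)
}

#' Deaths averted versus the flatline counterfactual
#'
#' @param scenario_proj,flatline_proj `population_projection` objects from
#'   the same profile and years.
#' @return Tibble (cause, year, averted): flatline deaths minus scenario
#'   deaths per cause-year, with stillbirths included as a pseudo-cause.
#' @export
deaths_averted <- function(scenario_proj, flatline_proj) {
  if (!identical(scenario_proj$years, flatline_proj$years) ||
      !identical(dim(scenario_proj$deaths), dim(flatline_proj$deaths)))
    stop("projections must share years and structure", call. = FALSE)
  by_cause <- function(p) apply(p$deaths, c(3, 4), sum)
  dd <- by_cause(flatline_proj) - by_cause(scenario_proj)
  d <- as.data.frame.table(dd, stringsAsFactors = FALSE)
  names(d) <- c("cause", "year", "averted")
  sb <- tibble::tibble(cause = "stillbirth",
                       year = as.character(scenario_proj$years),
                       averted = unname(flatline_proj$stillbirths -
                                          scenario_proj$stillbirths))
  out <- dplyr::bind_rows(sb, tibble::as_tibble(d))
  out$year <- as.integer(out$year)
  out
}

#' Abridged life table
#'
#' Standard abridged conversion from central death rates: probabilities
#' `q = n m / (1 + (n - a) m)` with separation factors `a = 0.3 n` for the
#' infant band, `n/2` for interior bands, and `1/m` for the open band
#' (`q = 1`, `L = l/m`).  Life expectancy at birth is `e0 = T0 / l0`.
#'
#' @param m Central death rates per band (all > 0 in the open band).
#' @param widths Band widths (default the 19-band structure).
#' @param a0_frac Infant separation factor as a fraction of the band width.
#' @return Tibble with columns `n`, `m`, `a`, `q`, `l`, `d`, `L`, `T`, `e`;
#'   `e[1]` is life expectancy at birth.
#' @export
life_table <- function(m, widths = age_bands()$width, a0_frac = 0.3) {
  nb <- length(m)
  stopifnot(length(widths) == nb)
  if (any(!is.finite(m[-nb])) || any(m < 0))
    stop("rates must be finite and >= 0", call. = FALSE)
  if (!is.finite(m[nb]) || m[nb] <= 0)
    stop("open-ended band requires a positive rate", call. = FALSE)
  n <- widths
  a <- ifelse(seq_len(nb) == 1L, a0_frac * n, n / 2)
  q <- n * m / (1 + (n - a) * m)
  q[nb] <- 1
  q <- pmin(q, 1)
  l <- cumprod(c(1, 1 - q[-nb]))
  d <- l * q
  L <- n * (l - d) + a * d
  L[nb] <- l[nb] / m[nb]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)
  tibble::tibble(band = if (nb == 19) age_bands()$band else as.character(seq_len(nb)),
                 n = n, m = m, a = a, q = q, l = l, d = d, L = L, T = Tx, e = e)
}

# all-cause central rates by band (sexes pooled, population-weighted)
pooled_rates <- function(hazard, population) {
  w <- population
  tot <- rowSums(w)
  r <- rowSums(hazard * w) / ifelse(tot > 0, tot, 1)
  r[tot == 0] <- rowMeans(hazard)[tot == 0]
  r
}

#' All-cause mortality rates implied by a projection year
#'
#' @param proj A `population_projection`.
#' @param year Calendar year.
#' @return Vector of pooled-sex central rates per band.
#' @export
projection_rates <- function(proj, year) {
  t <- match(year, proj$years)
  if (is.na(t)) stop("year outside projection range", call. = FALSE)
  pooled_rates(proj$hazard[, , t], proj$population[, , t])
}

#' @rdname projection_rates
#' @param profile A [country_profile()]; returns its 2015 baseline rates.
#' @export
baseline_rates <- function(profile) {
  M <- apply(profile$mortality_base, c(1, 2), sum)
  pooled_rates(M, profile$population_base)
}

#' Life-expectancy gains against two comparators
#'
#' @param scenario_lt Life table of the scenario in 2030.
#' @param flatline_lt Life table of the flatline counterfactual in 2030.
#' @param baseline_lt Life table of the 2015 baseline.
#' @return List with `gain_vs_2015` (scenario 2030 e0 minus 2015 e0) and
#'   `gain_vs_flatline` (scenario 2030 e0 minus flatline 2030 e0, the more
#'   conservative attribution).
#' @export
le_gains <- function(scenario_lt, flatline_lt, baseline_lt) {
  if (!identical(scenario_lt$n, flatline_lt$n) ||
      !identical(scenario_lt$n, baseline_lt$n))
    stop("life tables must share the same band structure", call. = FALSE)
  list(gain_vs_2015 = unname(scenario_lt$e[1] - baseline_lt$e[1]),
       gain_vs_flatline = unname(scenario_lt$e[1] - flatline_lt$e[1]))
}

#' Default morbidity conditions for healthy-life-year accounting
#'
#' Each condition carries a population prevalence, a disability weight, the
#' programme whose coverage expansion reduces it, and the proportional
#' prevalence reduction at full incremental coverage.
#'
#' @return Tibble (condition, program, prevalence, disability_weight,
#'   reduction_factor).
#' @export
default_conditions <- function() {
  tibble::tribble(
    ~condition,            ~program,        ~prevalence, ~disability_weight, ~reduction_factor,
    "anaemia_pregnancy",   "RMNCH",         0.15,        0.06,               0.5,
    "vaccine_preventable", "immunisation",  0.04,        0.10,               0.7,
    "hiv_morbidity",       "HIV",           0.012,       0.15,               0.6,
    "tb_morbidity",        "TB",            0.004,       0.30,               0.7,
    "malaria_morbidity",   "malaria",       0.05,        0.05,               0.6,
    "ntd_morbidity",       "NTD",           0.05,        0.10,               0.6,
    "cvd_copd_diabetes",   "NCD",           0.08,        0.20,               0.4,
    "mental_neuro_subst",  "mental_health", 0.10,        0.25,               0.4,
    "stunting_wasting",    "nutrition",     0.20,        0.06,               0.4)
}

cause_program_map <- function() {
  c(stillbirth = "RMNCH", neonatal = "RMNCH", post_neonatal = "RMNCH",
    maternal = "RMNCH", cancer = "NCD", cvd_ncd = "NCD",
    tuberculosis = "TB", hiv_aids = "HIV", malaria = "malaria",
    other = "other")
}

#' Healthy life-years gained versus the flatline counterfactual
#'
#' Healthy life-years in year t are `sum(pop(t) * (1 - sum(prevalence *
#' weight)))`; condition prevalences respond to coverage expansion through
#' programme-level prevalence-reduction factors.  The annual gain is the
#' scenario value minus the flatline value, decomposed into a morbidity
#' component (attributed to each condition's programme) and a mortality
#' component (extra survivors, attributed to programmes by their share of
#' deaths averted that year).
#'
#' @param scenario_proj,flatline_proj `population_projection` objects.
#' @param coverage_scen,coverage_flat Coverage matrices.
#' @param catalogue Intervention catalogue (programme membership).
#' @param conditions Tibble as [default_conditions()].
#' @return List: `by_year` tibble (year, hly_scenario, hly_flatline, gain)
#'   and `by_program` tibble (year, program, gain).
#' @export
healthy_life_years <- function(scenario_proj, flatline_proj,
                               coverage_scen, coverage_flat, catalogue,
                               conditions = default_conditions()) {
  stopifnot(all(conditions$disability_weight >= 0),
            all(conditions$disability_weight <= 1))
  years <- scenario_proj$years; ny <- length(years)
  # mean coverage increase over the counterfactual, per programme-year
  baseline_cov <- coverage_flat[, 1]
  prog_dcov <- function(covm) {
    d <- pmax(covm - baseline_cov, 0)
    cnt <- as.vector(table(catalogue$program)[sort(unique(catalogue$program))])
    rowsum(d, catalogue$program) / cnt
  }
  dc_s <- prog_dcov(coverage_scen); dc_f <- prog_dcov(coverage_flat)
  prev_mat <- function(dc) {
    sapply(seq_len(ny), function(t) {
      red <- numeric(nrow(conditions))
      hit <- conditions$program %in% rownames(dc)
      red[hit] <- dc[conditions$program[hit], t]
      pmax(0, conditions$prevalence * (1 - conditions$reduction_factor * red))
    })
  }
  if (nrow(conditions) == 0) {
    pv_s <- pv_f <- matrix(0, 0, ny)
    D_s <- D_f <- numeric(ny)
  } else {
    pv_s <- matrix(prev_mat(dc_s), nrow(conditions), ny)
    pv_f <- matrix(prev_mat(dc_f), nrow(conditions), ny)
    D_s <- colSums(pv_s * conditions$disability_weight)
    D_f <- colSums(pv_f * conditions$disability_weight)
  }
  if (any(D_s > 1) || any(D_f > 1))
    stop("combined disability exceeds 1; pre-combine condition weights", call. = FALSE)
  pop_s <- unname(apply(scenario_proj$population, 3, sum))
  pop_f <- unname(apply(flatline_proj$population, 3, sum))
  hly_s <- pop_s * (1 - D_s); hly_f <- pop_f * (1 - D_f)
  by_year <- tibble::tibble(year = years, hly_scenario = hly_s,
                            hly_flatline = hly_f, gain = hly_s - hly_f)
  # morbidity gains per condition-year -> programme
  morb <- (pv_f - pv_s) * conditions$disability_weight
  morb_gain <- sweep(morb, 2, pop_s, `*`)
  morb_tbl <- tibble::tibble(
    year = rep(years, each = nrow(conditions)),
    program = rep(conditions$program, ny),
    gain = as.vector(morb_gain))
  # mortality gains attributed by deaths-averted shares
  da <- deaths_averted(scenario_proj, flatline_proj)
  da$program <- unname(cause_program_map()[da$cause])
  mort_total <- pmax(0, (pop_s - pop_f) * (1 - D_f))
  shares <- da %>% dplyr::group_by(year, .data$program) %>%
    dplyr::summarise(averted = sum(.data$averted), .groups = "drop_last") %>%
    dplyr::mutate(share = {
      pos <- pmax(.data$averted, 0)
      if (sum(pos) > 0) pos / sum(pos) else rep(1 / dplyr::n(), dplyr::n())
    }) %>%
    dplyr::ungroup()
  mort_tbl <- shares %>%
    dplyr::mutate(gain = .data$share * mort_total[match(.data$year, years)]) %>%
    dplyr::select(year, program, gain)
  by_program <- dplyr::bind_rows(morb_tbl, mort_tbl) %>%
    dplyr::group_by(year, program) %>%
    dplyr::summarise(gain = sum(.data$gain), .groups = "drop")
  list(by_year = by_year, by_program = by_program)
}
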