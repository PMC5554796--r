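# Independent oracles: plain-loop reimplementations used to cross-check the
# package's vectorised code paths.

# abridged life expectancy at birth, sequential band-by-band arithmetic
oracle_e0 <- function(m, widths, a0_frac = 0.3) {
  nb <- length(m)
  l <- 1
  Tsum <- 0
  for (i in seq_len(nb - 1)) {
    n <- widths[i]
    a <- if (i == 1) a0_frac * n else n / 2
    q <- n * m[i] / (1 + (n - a) * m[i])
    d <- l * q
    Tsum <- Tsum + n * (l - d) + a * d
    l <- l - d
  }
  Tsum + l / m[nb]
}

# hand-stepped cohort projection: scalar loops over bands, sexes, causes
oracle_project <- function(pop0, mort, fert, widths, nyears, srb = 1.05,
                           adjust = NULL) {
  nb <- nrow(pop0); nc <- dim(mort)[3]
  pop <- pop0
  pop_out <- array(0, c(nb, 2, nyears))
  deaths_out <- array(0, c(nb, 2, nc, nyears))
  for (t in seq_len(nyears)) {
    pop_out[, , t] <- pop
    nxt <- matrix(0, nb, 2)
    for (s in 1:2) {
      for (b in 1:nb) {
        M <- 0
        for (k in 1:nc) {
          mk <- mort[b, s, k]
          if (!is.null(adjust)) mk <- mk * adjust[b, s, k, t]
          M <- M + mk
        }
        dead <- pop[b, s] * (1 - exp(-M))
        for (k in 1:nc) {
          mk <- mort[b, s, k]
          if (!is.null(adjust)) mk <- mk * adjust[b, s, k, t]
          deaths_out[b, s, k, t] <- if (M > 0) dead * mk / M else 0
        }
        surv <- pop[b, s] - dead
        adv <- if (is.finite(widths[b])) surv / widths[b] else 0
        nxt[b, s] <- nxt[b, s] + surv - adv
        if (b < nb) nxt[b + 1, s] <- nxt[b + 1, s] + adv
      }
    }
    births <- sum(fert * pop[, 1])
    nxt[1, 1] <- nxt[1, 1] + births * (1 / (1 + srb))
    nxt[1, 2] <- nxt[1, 2] + births * (srb / (1 + srb))
    pop <- nxt
  }
  list(population = pop_out, deaths = deaths_out)
}

# greedy step-wise clipping trajectory: the first value is the baseline
# (2016 indexes the starting level), then add min(cap, remaining gap) yearly
oracle_clipped_path <- function(baseline, target, cap, n = 15) {
  v <- numeric(n)
  v[1] <- baseline
  for (i in seq_len(n - 1)) v[i + 1] <- v[i] + min(cap, target - v[i])
  v
}

# spreadsheet-style service costing: loop over interventions, years, cells
oracle_service_cost_total <- function(profile, catalogue, coverage, projection,
                                      price_multiplier = 1) {
  total <- 0
  years <- projection$years
  for (i in seq_len(nrow(catalogue))) {
    pr <- catalogue$pin_rule[[i]]
    for (t in seq_along(years)) {
      pin <- 0
      for (j in seq_len(nrow(pr))) {
        sx <- if (pr$sex[j] == "both") c("female", "male") else pr$sex[j]
        for (s in sx) pin <- pin + projection$population[pr$band[j], s, t] * pr$fraction[j]
      }
      direct <- pin * coverage[catalogue$intervention_id[i], t] *
        catalogue$units_per_case[i] * catalogue$unit_price[i] *
        price_multiplier * catalogue$health_sector_share[i]
      total <- total + direct * (1 + catalogue$program_cost_share[i])
    }
  }
  total
}

# brute-force typology decision table
oracle_typology <- function(conflict, fragility, capacity, fr_cut, c1, c2) {
  if (conflict) return("conflict")
  if (fragility >= fr_cut) return("vulnerable")
  if (capacity >= c2) return("hs3")
  if (capacity >= c1) return("hs2")
  "hs1"
}

# a tiny three-band single-cause toy for engine tests
toy_inputs <- function(mort_scale = 1, fert_level = 0) {
  pop0 <- matrix(c(1000, 3000, 6000, 1000, 3000, 6000), nrow = 3,
                 dimnames = list(c("b1", "b2", "b3"), c("female", "male")))
  mort <- array(mort_scale * c(0.01, 0.005, 0.05, 0.012, 0.006, 0.06),
                c(3, 2, 1),
                dimnames = list(c("b1", "b2", "b3"), c("female", "male"), "all"))
  fert <- c(0, fert_level, 0)
  widths <- c(1, 4, Inf)
  list(pop0 = pop0, mort = mort, fert = fert, widths = widths)
}
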