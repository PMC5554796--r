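# uhcproj

Scenario projection of health-service scale-up costs, health impact, and
financing gaps for low- and middle-income countries, 2016–2030.

## What it does, and for whom

Health ministries, global-health analysts and modellers routinely need an
answer to three linked questions: what would it cost to expand coverage of
essential health services toward universal health coverage, what health
would that expansion buy, and how much of the bill can domestic financing
plausibly carry? `uhcproj` implements the full projection chain behind that
kind of "price tag" analysis as tested, reusable R functions:

* **Country typologies.** Countries are classified into five groups —
  conflict-affected, vulnerable systems, and health-system categories 1–3 —
  that gate how fast coverage can expand (absorptive capacity).
* **Coverage trajectories.** Annual coverage paths per intervention over
  2016–2030, under an *ambitious* scenario (global targets, clipped at
  attainment frontiers such as 60% for NCD management and 95% for
  immunisation), a *progress* scenario (closing 80% of the gap), and the
  *flatline* counterfactual holding 2015 coverage constant. Policy and
  outreach platforms ramp linearly; clinical platforms follow logistic
  ramps clipped at typology-specific annual increments.
* **Bottom-up costing.** Ingredients-based service costs
  (population-in-need × coverage × units × price), workforce plans closing
  density gaps (salaries + training), infrastructure builds peaking in 2029,
  and system overheads — differenced against the flatline stream into
  incremental costs in constant 2014 US$.
* **Health impact.** A cohort-component demographic projection on 19
  abridged age bands with multiplicative mortality reductions
  (`m' = m · Π(1 − effectiveness·affected_fraction·Δcoverage)`), deaths
  averted by cause (stillbirths included as a pseudo-cause), abridged life
  tables (`q = n·m/(1+(n−a)·m)`) with life-expectancy gains against both
  the 2015 baseline and the flatline counterfactual, and healthy life-years
  (`Σ pop · (1 − Σ prevalence·weight)`).
* **Financing.** Fiscal-space projections under optimistic and moderate
  scenarios, and per-country financing gaps
  (`max(0, incremental cost − incremental space)`), with group summaries
  that average each country over its own gap years.
* **Synthetic data.** A seeded generator producing validated country
  profiles and a 187-intervention catalogue with the statistical structure
  the analysis assumes, plus a tiny deterministic worked fixture.

See `vignettes/resource-needs-model.Rmd` for the model's assumptions,
parameter defaults and limitations.

## Worked example

```r
library(uhcproj)

fx  <- worked_fixture()        # 2 hard-coded profiles, 3 interventions
run <- run_country(fx$profiles[[1]], fx$catalogue, fx$benchmarks,
                   scenario  = scenario_spec("ambitious"),
                   fscenario = financing_scenario("optimistic"))

phase_aggregate(run$incremental)$mean_annual_cost[3]  # 378711739
sum(run$impact$deaths_averted$averted)                # 22432 (2016-30)
run$impact$le_gains$gain_vs_flatline                  # 0.432 years
round(mean(run$gap$gap[run$gap$year >= 2026]))        # 58396007
```

For the fixture country ALPHA (10 million people, low-income, category 1),
scaling all three interventions to their frontiers costs about $379 million
per year during 2026–30 — roughly $31 per person in 2030 — averts about
22 400 deaths over the fifteen years, adds 0.43 years of life expectancy
over the flatline counterfactual, and leaves a mean annual financing gap of
about $58 million in 2026–30 even under optimistic financing.

A full synthetic study runs the same way:

```r
cfg       <- generator_config(seed = 1)          # 67 countries, 187 interventions
catalogue <- generate_interventions(cfg)
profiles  <- generate_profiles(cfg, catalogue)
runs      <- run_ensemble(profiles, catalogue)
export_tables(runs, "results/")                  # group tables + manifest
```

A thin command-line wrapper with `generate` / `run` / `report` verbs lives
at `inst/cli/uhcproj.R`.

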