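---
title: "Projecting health-service scale-up: the model behind uhcproj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting health-service scale-up: the model behind uhcproj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhcproj)
```

`uhcproj` projects, for a set of low- and middle-income country profiles,
what it would cost to scale up health-service coverage between 2016 and
2030, what health that scale-up would buy (deaths averted, life expectancy,
healthy life-years), and how much of the bill could plausibly be financed
domestically. This vignette is the package's own account of the model: its
structure, its assumptions, the parameters that matter, and what the
synthetic-data experiments do and do not demonstrate.

## Model structure

The pipeline runs per country and per scenario:

1. **Typology.** Countries are classified into five groups that gate how
   fast services can expand: conflict-affected, vulnerable systems, and
   health-system categories 1–3 (`classify_typology()`). Active conflict
   dominates; otherwise a fragility score and a `[0,1]` system-capacity
   composite are compared against configurable thresholds. Scores exactly
   at a cutpoint go to the higher-capacity class, a tie-break fixed so the
   classification is deterministic and monotone: raising capacity can never
   demote a country.
2. **Coverage trajectories.** Each intervention belongs to one of four
   delivery platforms. Population-wide policy measures and periodic
   schedulable/outreach services ramp linearly and reach their target by
   the attainment year in every typology. First-level and specialised
   clinical services follow a logistic ramp whose annual increase is capped
   by platform × typology absorptive-capacity limits (defaults rise from
   conflict to category 3). When the cap binds, the path rises at the full
   cap — catch-up toward the target is permitted — so under a tight cap the
   path is exactly `baseline + cumulative min(cap, remaining gap)`, and the
   2030 value is the capped maximum rather than the target. Targets are
   `min(global target, frontier cap)`, never below baseline: 0.60 for NCD
   and mental-health management, 0.95 for maternal/child and immunisation
   services by default. The *ambitious* scenario closes the whole gap; the
   *progress* scenario closes 80% of it (configurable); the *flatline*
   counterfactual holds 2015 coverage constant.
3. **Demographic impact.** A cohort-component projection advances 19
   abridged age bands (0, 1–4, five-year bands to 85+) one year at a time:
   survival `exp(-M)` on summed cause-specific hazards, a fraction
   `1/width` of each band's survivors ageing into the next band, births
   from age-specific fertility applied to start-of-year women, split 1.05
   male:female. Coverage increases reduce cause-specific mortality
   multiplicatively: each intervention contributes a factor
   `1 − effectiveness × affected_fraction × Δcoverage`, so stacking is
   order-independent and the adjusted rate never leaves `(0, m]`.
   Stillbirths are a pseudo-cause proportional to livebirths, so they can
   be counted among deaths averted. Need is dynamic: deaths averted enlarge
   later cohorts and hence later populations in need.
4. **Costing.** Service costs are ingredients-based: population in need ×
   coverage × units per case × unit price × country price multiplier ×
   health-sector share, plus a programme-support mark-up. Workforce costs
   close the gap between current and target density linearly to the
   attainment year (salaries on the full headcount, one-off training on new
   hires; headcount never falls). Infrastructure construction is phased
   with annual volumes proportional to elapsed years, so capital spending
   peaks in 2029 and the build completes before 2030; operating costs
   accrue on the cumulative built stock. Governance, health information,
   supply chain, emergency risk management and financing administration are
   either fixed US$ per person or a percentage of service costs.
   Incremental cost is the per-key difference between the scenario stream
   and the flatline stream. All amounts are constant 2014 US$, undiscounted
   and uninflated, and capital is charged in the year incurred — phase sums
   therefore read directly as cash needs, and the cost curve retains its
   2029 peak. An efficiency factor rescales whole cost streams for
   high/low-efficiency variants.
5. **Life tables and healthy life-years.** Abridged life tables use
   `q = n·m/(1 + (n − a)·m)` with separation factors `a = 0.3n` for the
   infant band, `n/2` for interior bands, and `1/m` for the open band
   (`L = l/m`). Life-expectancy gains are reported against two
   comparators: the 2015 baseline table and the flatline 2030 table (the
   more conservative attribution). Healthy life-years weight person-years
   by `1 − Σ prevalence × disability weight`; condition prevalences respond
   to programme-level coverage expansion through configurable
   prevalence-reduction factors.
6. **Financing.** GDP per person compounds at profile growth rates.
   Government health spending scales with GDP and the scenario's share
   paths, anchored as ratios to each country's baseline shares; the
   non-government component scales with GDP to a configurable elasticity.
   The *optimistic* scenario converges the health allocation linearly
   toward a normative 15% of government spending by 2030 and adds a small
   revenue uplift; the *moderate* scenario holds baseline shares. Available
   incremental financing is spending above the constant 2015 per-person
   level — so a zero-growth, no-reform country has zero space, while growth
   alone creates space even at constant shares. The financing gap is the
   positive part of incremental cost minus that space, and group summaries
   average each country over its own gap years only.

## Design choices where the design was open

* **Typology rule.** The two-score rule (fragility plus capacity) with
  configurable cutpoints is a transparent stand-in for classification
  criteria that are otherwise qualitative; defaults make all five classes
  reachable.
* **Ramp shapes.** Linear for the two fast platforms, increment-capped
  logistic for clinical platforms. The logistic shape matters only when
  the cap is slack; when it binds, behaviour is the greedy capped path
  described above. Both shapes are configurable per platform.
* **Progress-scenario targets** default to closing 80% of the
  baseline-to-ambitious gap, and benchmark (density) ambition scales the
  same way, so progress costs and effects are pointwise below ambitious.
* **Financing baseline.** The counterfactual for "incremental space" is
  the 2015 per-person expenditure level held constant. The alternative — a
  frozen-shares baseline applied to growing GDP — would assign the moderate
  scenario identically zero space and make every gap equal the full cost,
  which contradicts the framing of gaps against current spending plus
  growth.
* **Dynamic feedback.** Averted deaths feed back into future population in
  need (raising costs); prevalence reductions feed back only into the
  healthy-life-year computation, not into need, keeping incremental costs
  monotone in ambition.
* **Counterfactual accounting.** All-cause deaths averted are non-negative
  every year, but individual cause-years can dip slightly negative:
  survivors saved from one cause later die of competing causes. This is a
  property of honest counterfactual accounting, not an error.
* **Stillbirths** are carried as a birth-linked pseudo-cause so that
  deaths-averted tables can include them; whether a headline lives-saved
  figure includes stillbirths is an accounting convention, and the
  published table this package's checks use only reconciles when they are
  included.

## The synthetic generator

`generator_config()` fixes the study conditions: a 67-country ensemble
(4 conflict-affected, 11 vulnerable, 15/16/21 in categories 1–3; 28 low-,
21 lower-middle-, 18 upper-middle-income) and a 187-intervention catalogue
spread over eleven programme areas. Distribution families are chosen for
support correctness — log-normal GDP and prices, beta baseline coverage
(means by platform, scaled down for weaker typologies), gamma-perturbed
mortality around a stylised age schedule, truncated-normal growth — and
every draw is truncated into the type invariants, so generated profiles
always validate. One explicit integer seed threads through every draw;
the same seed reproduces the ensemble bit for bit.

Two generator choices deserve comment. First, affected fractions of
interventions targeting the same cause are rescaled to sum to a drawn
per-cause total (0.5–0.9): each intervention acts on its own slice of a
cause's deaths, which is what "affected fraction" means; without the
rescaling, dozens of independently drawn effects stacking multiplicatively
on one cause would produce absurd mortality collapse. Second, default unit
prices (log-normal, median $1.50) and units per case (1–6) are set so that
commodity spending does not dwarf system investment; with these defaults
roughly three quarters of incremental cost is health-system investment
(workforce and infrastructure dominating), the qualitative structure the
model is meant to exhibit.

What the synthetic ensemble does *not* show: statistical realism for any
actual country, out-of-pocket spending, disease-transmission dynamics
(incidence feedback is a reduced-form prevalence factor), equity
stratification, or migration. Passing tests on synthetic data demonstrate
internal correctness — oracle equivalence, conservation, monotonicity,
determinism — not predictive accuracy for real countries.

## Numerical conventions

* Coverage paths: first value indexes the 2016 starting level (equal to
  baseline); increments respect caps to 1e-12; values clipped to
  `[0, frontier cap]`.
* Survival uses `-expm1(-M)` for the death probability; cause-of-death
  splits are proportional to cause hazards within a cell.
* Rounding happens only at export: per-person values round half-up to the
  nearest dollar (58.5 becomes 59 — not banker's rounding); internal
  aggregation keeps full precision.
* Degenerate inputs: zero-width gaps produce constant trajectories; empty
  condition sets make healthy life-years equal person-years; groups with
  no financing gap report `n = 0` and zero means.
* Problem sizes in the shipped experiments: 50-country ensembles for
  ordering properties, the 67-country default for structural table checks,
  three-band toys for engine oracles. These sizes make the full suite run
  in a few minutes on one CPU while exercising every code path.

## Known limitations

The absorptive-capacity caps, overhead rules, benchmark unit costs and
financing share paths are stylised defaults, not country evidence; every
one is a configuration input. Life tables pool sexes. The impact model is
a reduced-form effectiveness abstraction: it cannot capture herd effects,
resistance, or treatment-as-prevention dynamics, and effectiveness entries
are inputs, never estimates. Costs contain no price inflation, exchange
dynamics or discounting by construction.
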