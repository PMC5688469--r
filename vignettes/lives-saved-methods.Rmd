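---
title: "Methods: counterfactual lives-saved modelling for health portfolios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual lives-saved modelling for health portfolios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livessaved)
```

## The estimation problem

A donor's portfolio of maternal, newborn and family-planning projects
changes the population coverage of health interventions. The package
estimates the maternal and newborn deaths averted by those coverage
changes, attributing to the funder only its share of each increment, by
differencing two deterministic cohort projections per analysis unit: the
observed (or forecast) with-funder trajectory and a without-funder
counterfactual. The approach trades the precision of direct mortality
measurement — infeasible annually across dozens of countries — for a
transparent model whose every input is auditable.

## Cohort model

### Mortality

Deaths from cause $c$ in year $t$ are

$$D_{t,c} = B_t \cdot r_0 \cdot f_c \cdot
  \frac{\prod_i \bigl(1 - E_{i,c}\, A_{i,c}\, v_{i,t}\bigr)}
       {\prod_i \bigl(1 - E_{i,c}\, A_{i,c}\, v_{i,2010}\bigr)}$$

with $B_t$ live births, $r_0$ the baseline mortality level (NMR per
live birth for neonates, MMR per live birth for mothers), $f_c$ the
cause-of-death fraction, $v_{i,t}$ the coverage of intervention $i$,
$E_{i,c}$ its effectiveness against cause $c$ (proportional mortality
reduction at full coverage) and $A_{i,c}$ the affected fraction (the
share of that cause's deaths the intervention can address, defaulting
to 1 when a library entry omits it).

Three properties motivate this *multiplicative residual* form:

- each single intervention acts linearly in its coverage change, the
  assumption underlying effectiveness estimates from intervention
  trials;
- combined effects can never exceed 100% of a cause's deaths, however
  many interventions stack;
- normalizing by the baseline residual makes the model reproduce the
  baseline mortality rates exactly whenever coverage does not change,
  so a null portfolio yields exactly zero lives saved.

Interventions are applied along the continuum of care (pre-pregnancy,
pregnancy, childbirth, postnatal; preventive before curative within a
period). Because the residual is a product, results are invariant to
that order; the ordering is retained purely for reporting. This is a
deliberate simplification of sequential-application schemes: with a
multiplicative cascade the sequence carries no information, and we
prefer the order-invariant form to an order-dependent one whose
ordering would be unverifiable.

A degenerate input is rejected rather than patched: if an
effectiveness-1 effect sits at full baseline coverage the baseline
residual is zero and the normalization is undefined; `run_projection`
stops with an explanatory error.

### Fertility

Births follow the proximate-determinants (Bongaarts) index of
contraception $C_c = 1 - 1.08\,u\,e$, with $u$ contraceptive
prevalence, $e$ average use-effectiveness (default 0.9, the
conventional value) and 1.08 the standard adjustment for overlap with
lactational infecundability:

$$B_t = W \cdot \frac{TFR_0}{35} \cdot \frac{C_c(u_t)}{C_c(u_0)}
        \cdot s$$

where $W$ is women of reproductive age, 35 years the reproductive span
converting a total fertility rate to annual births, and $s$ the
analysis unit's share of national births. This is the simplest form
consistent with the family-planning modules of standard projection
software; parameter combinations implying a non-positive index
($1.08\,u\,e \ge 1$) are rejected. Maternal risk is denominated per
live birth, so fertility-mediated maternal savings emerge automatically
from reduced births; per-pregnancy refinements (abortion, stillbirth
denominators) are out of scope.

### Decomposition and attribution

Lives saved are the annual difference in deaths between the
without-funder and with-funder projections, summed strictly over the
post-baseline years. A secondary projection pair holds contraceptive
prevalence at its with-funder path in both members; its maternal lives
saved are the *direct health* component, and the remainder of the full
pair's maternal total is the *family planning* component. Any
interaction between the two pathways is thereby folded into the family
planning term — an arbitrary but explicit convention, isolated in one
operation, which makes the decomposition additive by construction.
Newborn lives saved through reduced fertility are computed the same way
but reported as an auxiliary series excluded from the headline newborn
total: a death that never occurs because a birth never occurs is not a
newborn life "saved".

Per-intervention attribution splits each (group, cause, year) cell of
deaths averted into a fertility part $(B_{wo} - B_w)\,r_{wo}$ credited
to family-planning interventions (proportionally to their prevalence
increments) and a health part $B_w (r_{wo} - r_w)$ shared across
interventions by their log-residual increments
$\log(1 - E A v_{wo}) - \log(1 - E A v_w)$. Log shares are exact for
the multiplicative cascade: they sum to the cell's health part, so the
attribution conserves the total by construction (asserted at 1e-6).
Leave-one-out marginals are a different, equally defensible
decomposition; the test suite checks that both allocate the same
total.

## Protocol choices where the design was open

- **Counterfactual formula.** The without-funder trajectory anchors at
  the 2010 baseline and scales each coverage increment by one minus the
  attribution fraction: $v^{cf}_t = v_0 + (1-a)(v_t - v_0)$, and
  identically for contraceptive prevalence. This reproduces both limits
  (full attribution ⇒ counterfactual at baseline; zero attribution ⇒
  counterfactual equals the actual trajectory, hence zero lives saved)
  and never drops coverage below the 2010 baseline when coverage rose.
  Whether a counterfactual should ever fall below baseline is
  genuinely undecidable from the protocol description; we chose not.
- **Heterogeneous attributions within a unit.** Merging happens across
  projects with different attribution fractions, so the counterfactual
  transform is applied per project fragment (each with its own
  attribution) *before* the merge, and both scenarios are merged with
  the same maximum rule. Attribution is uniform across a project's
  interventions, but the register carries it per row, so sector-specific
  overrides are expressible.
- **De-duplication by maximum.** Overlapping fragments for one
  (geography, intervention, year) are merged by maximum, never summed —
  the conservative choice against double counting of a single activity
  reported by several projects.
- **Missing years.** Years inside the horizon with no reported value
  for an intervention stay at baseline coverage in both scenarios: no
  evidence of activity, no claimed effect.
- **Achieved vs forecast.** Achieved values always beat forecasts in
  the same year. `achieved` mode truncates the horizon at the latest
  year with any achieved value; `forecast` mode extends to the profile
  horizon, using forecasts where no achievement is quantified.
- **Indicator conversion.** Commodities and services delivered divide
  by target population — assuming all supplies reach their targets,
  which overstates coverage and is flagged by a clip warning whenever
  the ratio exceeds 1. Message-exposure counts convert with a
  behaviour-change factor defaulting to 1 (exposure counted as
  coverage); set `behaviour_conversion` below 1 to model drop-off.
  Milestones carry no coverage and are reported only, as no defensible
  conversion exists.
- **Rounding.** Round-summary percentages round half away from zero
  (e.g. 12.5% → 13%), the convention consistent with all published
  per-round inclusion figures; one early-round figure in the source
  material (11/19 printed as 57%) is inconsistent with any nearest-
  integer rule and is not targeted.
- **Negative lives saved** (a with-funder scenario with higher
  mortality) are reported with a warning, never clipped.

## Synthetic data and what the tests show

No real country-office registers are published, so validation runs
entirely on synthetic data whose ground truth is known by construction.
The generator emulates the reporting template's heterogeneity: mixed
indicator types (roughly half coverage, the rest services, commodities,
message exposure and milestones), achieved values through a per-project
cut-over year (2012–2014) with forecasts beyond, national and
subnational geographies, deliberate duplicate reporting, and known
fractions of multilateral (10%), unmodelable (10%) and no-data (5%)
projects. Country baselines are drawn once per seed from ranges a field
epidemiologist would call typical of high-burden settings — NMR
15–60/1000, MMR 100–900/100k, TFR 2–7, contraceptive prevalence
5–45%, 3–6 causes per outcome group with Dirichlet fractions —
and effectiveness values span 0.05–0.95 with affected fractions
0.5–1.

Two independent implementations check the pipeline. The *closed-form
truth* re-derives every step — screening through attribution — in plain
brute-force loops sharing no code with the engine or protocol; the
pipeline must agree within 1e-6 absolute on every annual series (it
agrees at ~1e-12; this exactness check caught a real indexing bug
during development). The *microsimulation oracle* simulates each birth's
cause-specific death risk and per-effect exposure Bernoulli draws,
normalized by the same baseline residual; the engine must agree within
3 Monte-Carlo standard errors on each scenario's total deaths per
outcome group, with a 5-SE per-year guard against gross bias. The
aggregate-level comparison is used because with ~120 per-year
comparisons a bias-free engine exceeds 3 SE somewhere by chance alone
in roughly a quarter of runs.

Validation problem sizes, chosen to exercise every code path while
keeping the default suite quick: 20 seeded registers (3 countries, 12
projects each, both modes) for truth recovery; 10+ scenarios at 200,000
simulated births per year for the oracle; 100 seeds for generator
invariants. The whole suite runs in well under a minute.

Passing these tests shows the arithmetic chain is implemented as
specified — it says nothing about whether the model is *true* of any
real programme. In particular the synthetic data cannot surface the
real-world failure modes the protocol itself flags: aspirational
forecasts used as achievements, commodities that never reach targets,
tracer indicators understating whole programmes, or attribution
fractions of uneven quality.

## Tunable parameters

| Parameter | Units / default | Notes |
|---|---|---|
| `attribution` | fraction, per project row | funder share of each coverage increment |
| `population_share` | fraction of national births, 1 for national | scales births of subnational units |
| `behaviour_conversion` | fraction, 1.0 | message-exposure → behaviour drop-off |
| `contraceptive_effectiveness` | fraction, 0.9 | Bongaarts use-effectiveness |
| `mode` | `achieved` / `forecast` | horizon and value-precedence rule |
| `mortality_source` | label, `IGME` default | baseline NMR/MMR substitution in sensitivity runs |

Floating-point conservation assertions (decomposition additivity,
attribution totals, aggregation) use 1e-6 absolute on counts.

## Sensitivity analysis

`run_mortality_sensitivity` reruns the full pipeline once per mortality
source, substituting only the baseline NMR/MMR. Because deaths are
linear in the baseline rate for fixed trajectories, newborn totals
scale exactly with the substituted NMR and maternal totals with the
MMR — an assertable invariant, tested. The reported range is the
min/max of the global totals across source labels (range of sums, not
sum of ranges; per-country combination rules are not identifiable from
the protocol description).

## Known limitations

- Effectiveness and affected-fraction values carry no uncertainty
  intervals; the only reported uncertainty is the mortality-source
  range.
- The compact intervention library is configurable but far smaller than
  a full intervention-effectiveness database; results depend entirely
  on the values supplied.
- Geographic overlap is resolved by shared geography labels only; the
  package has no notion of partially overlapping areas.
- Women of reproductive age default to a constant; secular demographic
  trends must be supplied as per-year values if they matter.
- Stillbirths, child mortality beyond the neonatal period, HIV
  programme linkage and quality-of-care adjustments are out of scope.
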