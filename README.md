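# livessaved

Counterfactual lives-saved modelling for maternal and newborn health
portfolios.

## The problem

Donors that fund maternal, newborn and family-planning programmes across
many low- and middle-income countries are routinely asked how many lives
their portfolio saved. Measuring that directly would require repeated
large-scale mortality surveys in every country; in practice the
defensible alternative is a deterministic cohort model that links the
coverage changes a portfolio achieved to cause-specific mortality, and
compares a *with-funder* projection against a *without-funder*
counterfactual in which the funder's share of each coverage increment is
removed.

`livessaved` implements that protocol end to end for analysts working
with heterogeneous country-office project registers:

1. **Screening** — only bilateral, country-office-managed projects with
   at least one modellable intervention and some data are analysed;
   centrally managed and multilateral funding is excluded to avoid
   double counting.
2. **Grouping** — projects sharing a geography within a country form one
   analysis unit; overlapping reports of the same activity are merged by
   maximum, never summed.
3. **Indicator conversion** — coverage passes through; services
   delivered and commodities are divided by target population;
   message-exposure counts are damped by a configurable
   behaviour-change factor; milestones are reported but carry no
   coverage. Achieved values always beat forecasts.
4. **Counterfactual** — per project, `cov_cf = cov0 + (1 - a)(cov - cov0)`
   where `a` is the funder's attribution fraction.
5. **Projection** — a compact LiST-style cohort engine (below) run on
   both members of the pair, annually differenced and summed over the
   post-baseline years (2011–2015 by default).
6. **Decomposition, attribution, aggregation, sensitivity** — family
   planning vs direct health, per-intervention shares, unit → country →
   global sums, and reruns across alternative baseline mortality sources
   (IGME, IHME, DHS, ...).

## The model

For a cause *c* of neonatal or maternal death, annual deaths are

```
deaths(t, c) = births(t) · r0 · f(c) · RF(cov_t, c) / RF(cov_2010, c)
```

where `r0` is the baseline NMR (per live birth) or MMR (per live
birth), `f(c)` the cause fraction, and the residual factor

```
RF(cov, c) = Π_i ( 1 − E_i(c) · AF_i(c) · cov_i )
```

multiplies interventions *i* along the continuum of care
(pre-pregnancy → pregnancy → childbirth → postnatal, preventive before
curative; the product makes the result order-invariant). `E` is the
effectiveness — the proportional cause-specific mortality reduction at
full coverage — and `AF` the affected fraction. Normalizing by the
baseline residual means an unchanged trajectory reproduces baseline
rates exactly.

Births respond to contraceptive prevalence `u` through the Bongaarts
index of contraception `Cc = 1 − 1.08·u·e`:

```
births(t) = W · (TFR0 / 35) · Cc(u_t) / Cc(u_2010) · share
```

so family-planning coverage feeds fertility, which feeds both maternal
deaths (per live birth) and an auxiliary fertility-mediated newborn
series that is reported separately and excluded from the headline
newborn total. A secondary projection pair with contraceptive
prevalence pinned at its with-funder path isolates the direct-health
component; the family-planning component is the remainder, so the
maternal decomposition is additive by construction.

Everything is validated against two independent implementations: a
closed-form brute-force recomputation (`closed_form_truth`, exact to
1e-6) and a per-birth Monte-Carlo microsimulation
(`microsim_oracle`, within Monte-Carlo error).

## Worked example

A small synthetic register, intervention library and country profiles
ship under `inst/extdata/` (country `C01`: NMR 44.7/1000, MMR
631/100k, TFR 4.2, contraceptive prevalence 7.7%):

```r
library(livessaved)

reg  <- read_project_register(system.file("extdata", "register.csv",  package = "livessaved"))
lib  <- read_intervention_library(system.file("extdata", "library.yaml", package = "livessaved"))
prof <- read_country_profile(system.file("extdata", "profiles/C01.yaml", package = "livessaved"))

res <- run_country_analysis(reg[reg$country_id == "C01", ], prof, lib,
                            mode = "forecast")
res
#> <lives_saved_result> C01, 5 year(s), 1 analysis unit(s)
#>   maternal: 442.6 total (319.5 family planning + 123.1 direct health)
#>   newborn:  12.6 primary (+ 2352.5 fertility-mediated, auxiliary)

round(res$per_intervention, 1)
#> fp_modern_methods           intv_02           intv_08           intv_11
#>            2672.0               8.3              51.3              76.1
```

Reading: over 2011–2015 the portfolio's projected coverage gains saved
about 443 mothers in this country — 320 through reduced fertility
(family planning) and 123 through direct health interventions — and
13 newborns through direct health effects; a further ~2353 newborn
deaths are averted only because fewer births occur, which the protocol
reports separately and keeps out of the headline. The per-intervention
shares sum to the full total (maternal plus both newborn components)
and are allocated by log-residual increments, with the
fertility-mediated part credited to the family-planning intervention.

The same analysis runs from a shell:

```sh
inst/scripts/livessaved run --register inst/extdata/register.csv \
  --profiles inst/extdata/profiles --library inst/extdata/library.yaml \
  --mode forecast --out results/
```

## Scope

Stillbirths, child (1–59 month) mortality, HIV programme linkage,
nutrition pathways, quality-of-care adjustment and uncertainty
intervals beyond the mortality-source range are out of scope. See the
methods vignette (`vignettes/lives-saved-methods.Rmd`) for model
assumptions, parameter choices and limitations.
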