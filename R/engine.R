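#' Bongaarts index of contraception
#'
#' The proximate-determinants fertility index `Cc = 1 - 1.08 * u * e`,
#' where `u` is contraceptive prevalence and `e` the average
#' use-effectiveness; 1.08 is the conventional adjustment for overlap of
#' contraceptive use with lactational infecundability. Fertility is scaled
#' by the ratio of this index at current versus baseline prevalence.
#'
#' @param cp Contraceptive prevalence in `[0,1]`.
#' @param eff Use-effectiveness in `[0,1]`.
#' @return The index, in `(0,1]`.
#' @examples
#' bongaarts_index(0.3, 0.9) # 0.7084
#' @export
bongaarts_index <- function(cp, eff) {
  if (any(cp < 0) || any(cp > 1) || any(eff < 0) || any(eff > 1))
    stop("cp and eff must lie in [0,1]")
  idx <- 1 - 1.08 * cp * eff
  if (any(idx <= 0))
    stop("contraception parameters imply a non-positive fertility index")
  idx
}

# years the engine projects: baseline..horizon as stored in a trajectory
.span_years <- 35  # reproductive span used to convert TFR to annual births

#' Project annual births under a contraceptive-prevalence path
#'
#' Annual births are `W * (TFR0 / 35) * Cc(cp_t) / Cc(cp_0) * share`: the
#' baseline total fertility rate spread uniformly over a 35-year
#' reproductive span, rescaled by the ratio of the Bongaarts contraception
#' index at the year's prevalence to its baseline value, and scaled to the
#' analysis unit's share of national births.
#'
#' @param profile A [country_profile()].
#' @param cp Named numeric vector of contraceptive prevalence keyed by
#'   year; must cover every requested year.
#' @param population_share Share of national births in `(0,1]`.
#' @param years Years to project (default: every year named in `cp`).
#' @return Named numeric vector of births per year.
#' @export
project_births <- function(profile, cp, population_share = 1,
                           years = as.integer(names(cp))) {
  missing_years <- setdiff(as.character(years), names(cp))
  if (length(missing_years))
    stop("no contraceptive prevalence for year ", missing_years[1])
  e <- profile$contraceptive_effectiveness
  c0 <- bongaarts_index(profile$cp0, e)
  out <- vapply(years, function(y) {
    women_at(profile, y) * (profile$tfr0 / .span_years) *
      bongaarts_index(cp[[as.character(y)]], e) / c0 * population_share
  }, numeric(1))
  stats::setNames(out, as.character(years))
}

#' Residual mortality factor of an intervention portfolio
#'
#' For one target group and cause, the product over interventions of
#' `1 - effectiveness * affected_fraction * coverage` across matching
#' effects. Interventions are applied along the continuum of care
#' (pre-pregnancy, pregnancy, childbirth, postnatal; preventive before
#' curative within each period); the multiplicative form makes the result
#' independent of that order, which is retained only for reporting.
#' Interventions without a matching effect contribute factor 1.
#'
#' @param library An [intervention_library()].
#' @param coverage Named numeric vector of coverages in `[0,1]` keyed by
#'   intervention id; ids must exist in the library.
#' @param target_group `"neonatal"` or `"maternal"`.
#' @param cause Cause-of-death label.
#' @return The residual factor, in `(0,1]`.
#' @export
residual_factor <- function(library, coverage, target_group, cause) {
  unknown <- setdiff(names(coverage), names(library))
  if (length(unknown))
    stop("coverage given for unknown intervention: ", unknown[1])
  if (length(coverage) && (any(coverage < 0) || any(coverage > 1)))
    stop("coverages must lie in [0,1]")
  rf <- 1
  for (id in library_order(library)) {
    if (!id %in% names(coverage)) next
    eff <- library[[id]]$effects
    hit <- eff$target_group == target_group & eff$cause == cause
    if (!any(hit)) next
    rf <- rf * prod(1 - eff$effectiveness[hit] * eff$affected_fraction[hit] *
                      coverage[[id]])
  }
  rf
}

#' Run one deterministic cohort projection
#'
#' Computes annual births from the scenario's contraceptive-prevalence
#' path, then cause-specific neonatal and maternal deaths as
#' `births_t * baseline_rate * cause_fraction * RF(cov_t) / RF(cov_2010)`,
#' where `RF` is the multiplicative residual over intervention effects.
#' Normalizing by the baseline residual guarantees that an unchanged
#' trajectory reproduces the baseline mortality rates exactly.
#'
#' @param scn A [scenario()].
#' @param library An [intervention_library()].
#' @return An object of class `projection_result` with elements `births`
#'   (named numeric by year), `neonatal_deaths` and `maternal_deaths`
#'   (cause-by-year matrices), `years`, and `country_id`.
#' @export
run_projection <- function(scn, library) {
  stopifnot(inherits(scn, "scenario"))
  profile <- scn$profile
  traj <- scn$trajectory
  years <- traj$years
  births <- project_births(profile, traj$cp, scn$population_share, years)
  ids <- rownames(traj$cov)
  cov0 <- baseline_cov_for(profile, ids)

  groups <- list(
    neonatal = list(rate = profile$nmr0 / 1000,
                    fractions = profile$neonatal_cause_fractions),
    maternal = list(rate = profile$mmr0 / 1e5,
                    fractions = profile$maternal_cause_fractions)
  )
  deaths <- lapply(names(groups), function(g) {
    fr <- groups[[g]]$fractions
    rate <- groups[[g]]$rate
    m <- matrix(0, nrow = length(fr), ncol = length(years),
                dimnames = list(names(fr), as.character(years)))
    for (cause in names(fr)) {
      rf0 <- residual_factor(library, cov0, g, cause)
      if (rf0 == 0)
        stop("baseline coverage saturates an effect for cause '", cause,
             "': baseline residual factor is zero")
      for (y in as.character(years)) {
        cov_y <- stats::setNames(traj$cov[, y], rownames(traj$cov))
        rf <- residual_factor(library, cov_y, g, cause)
        m[cause, y] <- births[[y]] * rate * fr[[cause]] * rf / rf0
      }
    }
    m
  })
  names(deaths) <- names(groups)
  structure(list(births = births,
                 neonatal_deaths = deaths$neonatal,
                 maternal_deaths = deaths$maternal,
                 years = years,
                 country_id = profile$country_id,
                 baseline_year = profile$baseline_year),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result> ", x$country_id, ", years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  cat("  births: ", paste(round(x$births), collapse = ", "), "\n", sep = "")
  cat("  neonatal deaths/yr: ",
      paste(round(colSums(x$neonatal_deaths), 1), collapse = ", "),
      "\n  maternal deaths/yr: ",
      paste(round(colSums(x$maternal_deaths), 1), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Annual lives saved between paired projections
#'
#' The difference in deaths, summed over causes, between the
#' without-funder and with-funder members of a projection pair, reported
#' for every year strictly after the baseline year. Negative values (a
#' funder scenario with higher mortality) are reported with a warning, not
#' clipped.
#'
#' @param with_result,without_result `projection_result` objects sharing
#'   the same years.
#' @return A list with named numeric vectors `maternal` and `newborn`
#'   (lives saved per post-baseline year).
#' @export
lives_saved <- function(with_result, without_result) {
  if (!identical(with_result$years, without_result$years))
    stop("paired projections must share the same years")
  keep <- as.character(with_result$years[with_result$years >
                                           with_result$baseline_year])
  nn <- colSums(without_result$neonatal_deaths)[keep] -
    colSums(with_result$neonatal_deaths)[keep]
  mm <- colSums(without_result$maternal_deaths)[keep] -
    colSums(with_result$maternal_deaths)[keep]
  if (any(nn < -1e-9) || any(mm < -1e-9))
    warning("negative lives saved: the with-funder scenario has higher mortality in some year")
  list(maternal = mm, newborn = nn)
}

#' Disaggregate family-planning from direct-health impact
#'
#' Uses the secondary projection pair, in which contraceptive prevalence
#' is held at its with-funder path in both members, to isolate the direct
#' health effect; the family-planning (fertility-mediated) component is
#' the remainder of the full pair's lives saved. Any interaction between
#' the two pathways is folded into the family-planning component, so
#' `maternal_fp + maternal_health` equals the full pair's maternal lives
#' saved exactly by construction. Newborn lives saved via reduced
#' fertility are reported separately and excluded from the primary newborn
#' series.
#'
#' @param full_with,full_without Projections in which both coverage and
#'   contraceptive prevalence differ between scenarios.
#' @param health_with,health_without The secondary pair (contraceptive
#'   prevalence pinned at with-funder values in both).
#' @return A list of annual named vectors: `maternal_total`,
#'   `maternal_fp`, `maternal_health`, `newborn_primary`,
#'   `newborn_fertility`.
#' @export
decompose_fp_health <- function(full_with, full_without,
                                health_with, health_without) {
  cids <- vapply(list(full_with, full_without, health_with, health_without),
                 `[[`, character(1), "country_id")
  if (length(unique(cids)) != 1L)
    stop("projection pairs were built from different profiles")
  full <- lives_saved(full_with, full_without)
  health <- lives_saved(health_with, health_without)
  list(maternal_total = full$maternal,
       maternal_fp = full$maternal - health$maternal,
       maternal_health = health$maternal,
       newborn_primary = health$newborn,
       newborn_fertility = full$newborn - health$newborn)
}

#' Attribute lives saved to individual interventions
#'
#' Deaths averted in each (target group, cause, year) cell are split into
#' a direct-health part (the mortality-rate change at with-funder births)
#' and a fertility part (the births change at the counterfactual rate).
#' The health part is shared across interventions proportionally to their
#' log-residual increments
#' `log(1 - E*AF*cov_without) - log(1 - E*AF*cov_with)`; the fertility
#' part goes to the family-planning interventions in proportion to their
#' prevalence increments. Shares are conservative: they sum to the pair's
#' total lives saved (maternal plus newborn, fertility-mediated components
#' included) to within rounding.
#'
#' @param pair A list with `with` and `without` scenarios (class
#'   `scenario`) as built by [assemble_scenarios()], or any two scenarios
#'   passed as `pair = list(with = ..., without = ...)`.
#' @param library An [intervention_library()].
#' @return Named numeric vector of total lives saved per intervention id.
#' @export
per_intervention_attribution <- function(pair, library) {
  scn_w <- pair$with
  scn_wo <- pair$without
  res_w <- run_projection(scn_w, library)
  res_wo <- run_projection(scn_wo, library)
  years <- as.character(res_w$years[res_w$years > res_w$baseline_year])
  ids <- rownames(scn_w$trajectory$cov)
  out <- stats::setNames(rep(0, length(ids)), ids)
  fp <- intersect(ids, fp_ids(library))

  for (g in c("neonatal", "maternal")) {
    dmat_w <- if (g == "neonatal") res_w$neonatal_deaths else res_w$maternal_deaths
    dmat_wo <- if (g == "neonatal") res_wo$neonatal_deaths else res_wo$maternal_deaths
    for (y in years) {
      b_w <- res_w$births[[y]]
      b_wo <- res_wo$births[[y]]
      for (cause in rownames(dmat_w)) {
        r_w <- dmat_w[cause, y] / b_w
        r_wo <- dmat_wo[cause, y] / b_wo
        health_part <- b_w * (r_wo - r_w)
        fert_part <- (b_wo - b_w) * r_wo
        if (abs(health_part) > 0) {
          w <- vapply(ids, function(id) {
            eff <- library[[id]]$effects
            hit <- eff$target_group == g & eff$cause == cause
            if (!any(hit)) return(0)
            sum(log1p(-eff$effectiveness[hit] * eff$affected_fraction[hit] *
                        scn_wo$trajectory$cov[id, y]) -
                log1p(-eff$effectiveness[hit] * eff$affected_fraction[hit] *
                        scn_w$trajectory$cov[id, y]))
          }, numeric(1))
          if (sum(w) != 0)
            out <- out + health_part * w / sum(w)
        }
        if (abs(fert_part) > 0) {
          if (length(fp) == 0)
            stop("fertility-mediated lives saved but no family-planning intervention in the portfolio")
          dcp <- scn_w$trajectory$cov[fp, y, drop = TRUE] -
            scn_wo$trajectory$cov[fp, y, drop = TRUE]
          w <- if (sum(dcp) != 0) dcp / sum(dcp) else rep(1 / length(fp), length(fp))
          out[fp] <- out[fp] + fert_part * w
        }
      }
    }
  }
  out
}
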