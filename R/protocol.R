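#' Screen a project register for analysable projects
#'
#' Applies the inclusion rules: only bilateral, country-office-managed
#' projects are analysed (centrally managed multi-country programmes and
#' direct multilateral funding are excluded to avoid double counting);
#' a project must report at least one intervention present in the
#' modelling library; and it must carry at least one non-missing annual
#' value for such an intervention. Screening never hard-fails: every
#' project lands in exactly one of the two output lists.
#'
#' @param register Project-register tibble (see [read_project_register()]).
#' @param library An [intervention_library()].
#' @return A list with `eligible` (register rows of retained projects) and
#'   `excluded` (tibble of `project_id`, `reason`).
#' @export
screen_projects <- function(register, library) {
  excluded <- list()
  keep <- character()
  for (pid in unique(register$project_id)) {
    rows <- register[register$project_id == pid, ]
    if (rows$management[1] != "bilateral") {
      excluded[[pid]] <- "central/multilateral"
    } else if (!any(rows$intervention_id %in% names(library))) {
      excluded[[pid]] <- "not modelable"
    } else if (all(is.na(rows$value[rows$intervention_id %in% names(library)]))) {
      excluded[[pid]] <- "no data"
    } else {
      keep <- c(keep, pid)
    }
  }
  list(
    eligible = register[register$project_id %in% keep, ],
    excluded = tibble::tibble(project_id = names(excluded),
                              reason = unlist(excluded, use.names = FALSE))
  )
}

#' Group eligible projects into analysis units
#'
#' Projects sharing a geography within one country are modelled together
#' as one analysis unit, so that geographically overlapping interventions
#' are merged and duplicated reporting of a single activity can be
#' removed. The geography label `"national"` denotes nationwide
#' programmes (population share 1); subnational units carry their stated
#' share of national births.
#'
#' @param eligible Register rows of screened-in projects.
#' @return A list of analysis units, each a list with `country_id`,
#'   `geography_ids`, `population_share`, and `entries` (register rows).
#' @export
group_analysis_units <- function(eligible) {
  units <- list()
  for (cid in sort(unique(eligible$country_id))) {
    crows <- eligible[eligible$country_id == cid, ]
    for (gid in sort(unique(crows$geography_id))) {
      grows <- crows[crows$geography_id == gid, ]
      if (identical(gid, "national")) {
        share <- 1
      } else {
        shares <- unique(round(grows$population_share, 9))
        if (length(shares) > 1)
          stop("conflicting population_share values for geography '", gid,
               "' in ", cid)
        share <- shares[[1]]
      }
      units[[length(units) + 1L]] <- list(
        country_id = cid,
        geography_ids = gid,
        population_share = share,
        entries = grows
      )
    }
  }
  units
}

#' Convert a reported indicator value to population coverage
#'
#' The register mixes indicator types. Coverage-type values pass through
#' unchanged; services-delivered and commodity counts are divided by the
#' target population (commodities are assumed to reach their intended
#' targets); message-exposure counts are additionally damped by a
#' configurable behaviour-change conversion factor (default 1, i.e.
#' exposure counted as coverage); milestone flags carry no coverage and
#' are reported only. Ratios exceeding 1 are clipped to 1 with a warning.
#'
#' @param value Reported annual value.
#' @param indicator_type One of `"coverage"`, `"services_delivered"`,
#'   `"commodities"`, `"message_exposure"`, `"milestone"`.
#' @param target_population Target population size; required for the
#'   ratio-type indicators.
#' @param behaviour_conversion Fraction of message-exposed individuals
#'   assumed to change behaviour, in `[0,1]`.
#' @param context Label used in error messages.
#' @return Coverage in `[0,1]`, or `NA` for milestones.
#' @export
indicator_to_coverage <- function(value, indicator_type,
                                  target_population = NA,
                                  behaviour_conversion = 1,
                                  context = "") {
  if (is.na(value)) return(NA_real_)
  switch(indicator_type,
    coverage = {
      if (value < 0 || value > 1)
        stop("coverage value outside [0,1] ", context)
      value
    },
    services_delivered = ,
    commodities = {
      if (is.na(target_population) || target_population <= 0)
        stop("missing target_population for ", indicator_type, " ", context)
      ratio <- value / target_population
      if (ratio > 1) {
        warning("clipping ", indicator_type, " ratio ",
                format(ratio, digits = 4), " to 1 ", context)
        ratio <- 1
      }
      ratio
    },
    message_exposure = {
      if (is.na(target_population) || target_population <= 0)
        stop("missing target_population for message_exposure ", context)
      ratio <- value / target_population * behaviour_conversion
      if (ratio > 1) {
        warning("clipping message_exposure ratio to 1 ", context)
        ratio <- 1
      }
      ratio
    },
    milestone = NA_real_,
    stop("unknown indicator_type '", indicator_type, "' ", context)
  )
}

#' Resolve achieved versus forecast values
#'
#' Achieved (observed) values always take precedence; forecast targets are
#' used only when no quantified achievement is available.
#'
#' @param achieved,forecast Optional numeric values (`NA` when absent).
#' @return A list with `value` and `provenance` (`"achieved"` or
#'   `"forecast"`).
#' @export
resolve_value <- function(achieved = NA, forecast = NA) {
  if (!is.na(achieved)) return(list(value = achieved, provenance = "achieved"))
  if (!is.na(forecast)) return(list(value = forecast, provenance = "forecast"))
  stop("neither an achieved nor a forecast value is available")
}

#' Merge overlapping coverage fragments
#'
#' When several projects report the same intervention, geography and year,
#' the merged coverage is the maximum of the fragments, never their sum:
#' overlapping reports are treated as duplicated reporting of one
#' activity, the conservative choice against double counting.
#'
#' @param fragments Numeric vector of coverage fragments (at least one).
#' @return The merged coverage.
#' @export
merge_coverage <- function(fragments) {
  fragments <- fragments[!is.na(fragments)]
  if (length(fragments) == 0) stop("merge_coverage needs at least one fragment")
  if (length(fragments) > 1)
    message("de-duplicating ", length(fragments),
            " overlapping coverage fragments (taking the maximum)")
  max(fragments)
}

# counterfactual arithmetic on a single value: anchor at the baseline and
# scale the increment by 1 - attribution.
cf_value <- function(cov, cov0, attribution) {
  cov0 + (1 - attribution) * (cov - cov0)
}

#' Build a without-funder counterfactual trajectory
#'
#' The counterfactual removes the funder's share of every coverage
#' increment: `cov_cf = cov_0 + (1 - attribution) * (cov - cov_0)` per
#' intervention-year, and identically for contraceptive prevalence. With
#' attribution 1 the counterfactual sits at the baseline; with
#' attribution 0 it reproduces the actual trajectory (and downstream
#' lives saved vanish). The counterfactual never drops below the 2010
#' baseline when coverage only rises.
#'
#' @param traj A [coverage_trajectory()] (the with-funder path).
#' @param baseline A [coverage_trajectory()] carrying the anchor values
#'   (typically constant at the 2010 baseline), with the same
#'   interventions and years.
#' @param attribution Funder attribution fraction in `[0,1]`.
#' @return The counterfactual [coverage_trajectory()].
#' @export
build_counterfactual <- function(traj, baseline, attribution) {
  if (attribution < 0 || attribution > 1)
    stop("attribution must lie in [0,1]")
  stopifnot(identical(dimnames(traj$cov), dimnames(baseline$cov)))
  coverage_trajectory(
    cf_value(traj$cov, baseline$cov, attribution),
    cf_value(traj$cp, baseline$cp[names(traj$cp)], attribution)
  )
}

# Resolve, convert and counterfactual-transform one analysis unit's
# register rows into per-fragment coverage records.
#   Returns a data frame: intervention_id, year, project_id, value (with-
#   funder coverage), cf (counterfactual coverage), provenance.
unit_fragments <- function(unit, profile, library, behaviour_conversion = 1) {
  rows <- unit$entries
  rows <- rows[rows$intervention_id %in% names(library) &
                 rows$indicator_type != "milestone" & !is.na(rows$value), ]
  if (nrow(rows) == 0)
    return(data.frame(intervention_id = character(), year = integer(),
                      project_id = character(), value = numeric(),
                      cf = numeric(), provenance = character()))
  out <- vector("list", 0)
  keys <- unique(rows[, c("project_id", "intervention_id", "year")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- rows[rows$project_id == k$project_id &
                  rows$intervention_id == k$intervention_id &
                  rows$year == k$year, ]
    ach <- sub[sub$provenance == "achieved", ]
    fc <- sub[sub$provenance == "forecast", ]
    res <- resolve_value(if (nrow(ach)) max(ach$value) else NA,
                         if (nrow(fc)) max(fc$value) else NA)
    src <- if (res$provenance == "achieved") ach else fc
    src <- src[which.max(src$value), ]
    cvg <- indicator_to_coverage(
      res$value, src$indicator_type, src$target_population,
      behaviour_conversion,
      context = sprintf("(project %s, intervention %s, year %s)",
                        k$project_id, k$intervention_id, k$year))
    if (is.na(cvg)) next
    cov0 <- unit_baseline_cov(profile, library, k$intervention_id)
    out[[length(out) + 1L]] <- data.frame(
      intervention_id = k$intervention_id, year = as.integer(k$year),
      project_id = k$project_id, value = cvg,
      cf = cf_value(cvg, cov0, src$attribution),
      provenance = res$provenance, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# baseline coverage for one intervention: contraceptive prevalence for
# family-planning interventions, the profile's baseline coverage (0 when
# unlisted) otherwise.
unit_baseline_cov <- function(profile, library, id) {
  if (library[[id]]$is_family_planning) return(profile$cp0)
  if (id %in% names(profile$baseline_coverage))
    return(unname(profile$baseline_coverage[[id]]))
  0
}

#' Assemble the paired projection scenarios for an analysis unit
#'
#' Resolves achieved-versus-forecast values, converts indicators to
#' coverage, applies each project's attribution to build the
#' without-funder counterfactual, merges overlapping fragments by maximum,
#' and assembles the primary with/without pair together with the
#' secondary health-only pair in which contraceptive prevalence is held at
#' its with-funder path in both members. In `"achieved"` mode the horizon
#' is truncated at the latest year with any achieved value; in
#' `"forecast"` mode it extends to the profile's horizon year, using
#' forecasts where no achievement is quantified. Years inside the horizon
#' with no reported value for an intervention stay at baseline coverage in
#' both scenarios.
#'
#' @param unit An analysis unit from [group_analysis_units()].
#' @param profile The country's [country_profile()].
#' @param library An [intervention_library()].
#' @param mode `"achieved"` or `"forecast"`.
#' @param behaviour_conversion Conversion factor for message-exposure
#'   indicators (see [indicator_to_coverage()]).
#' @return An object of class `scenario_pair`: scenarios `with`,
#'   `without`, `health_with`, `health_without`, plus `meta` (horizon,
#'   de-duplicated fragment count, milestone rows).
#' @export
assemble_scenarios <- function(unit, profile, library,
                               mode = c("achieved", "forecast"),
                               behaviour_conversion = 1) {
  mode <- match.arg(mode)
  frag <- unit_fragments(unit, profile, library, behaviour_conversion)
  horizon <- if (mode == "forecast") {
    profile$horizon_year
  } else {
    ach_years <- frag$year[frag$provenance == "achieved"]
    if (length(ach_years) == 0)
      stop("analysis unit has zero usable years in achieved mode (",
           unit$country_id, "/", unit$geography_ids, ")")
    min(max(ach_years), profile$horizon_year)
  }
  years <- seq(profile$baseline_year, horizon)
  if (length(years) < 2)
    stop("analysis unit has zero usable years (horizon at or before baseline)")
  frag <- frag[frag$year %in% years, , drop = FALSE]

  ids <- sort(unique(frag$intervention_id))
  cov0 <- vapply(ids, function(id) unit_baseline_cov(profile, library, id),
                 numeric(1))
  ykey <- as.character(years)
  cov_w <- matrix(rep(cov0, length(years)), nrow = length(ids),
                  ncol = length(years), dimnames = list(ids, ykey))
  cov_wo <- cov_w
  n_dup <- 0L
  for (id in ids) {
    for (y in years[-1]) {
      cell <- frag[frag$intervention_id == id & frag$year == y, ]
      if (nrow(cell) == 0) next
      if (nrow(cell) > 1) n_dup <- n_dup + nrow(cell) - 1L
      cov_w[id, as.character(y)] <- max(cell$value)
      cov_wo[id, as.character(y)] <- max(cell$cf)
    }
  }

  fp <- intersect(ids, fp_ids(library))
  cp_w <- stats::setNames(rep(profile$cp0, length(years)), ykey)
  cp_wo <- cp_w
  if (length(fp)) {
    cp_w[ykey[-1]] <- apply(cov_w[fp, ykey[-1], drop = FALSE], 2, max)
    cp_wo[ykey[-1]] <- apply(cov_wo[fp, ykey[-1], drop = FALSE], 2, max)
  }

  # the four scenarios share one profile whose family-planning baselines
  # are pinned at cp0, so that baseline-year validation holds
  prof <- profile
  if (length(fp))
    prof$baseline_coverage[fp] <- prof$cp0

  traj_w <- coverage_trajectory(cov_w, cp_w)
  traj_wo <- coverage_trajectory(cov_wo, cp_wo)
  traj_hwo <- coverage_trajectory(cov_wo, cp_w)
  milestones <- unit$entries[unit$entries$indicator_type == "milestone" &
                               !is.na(unit$entries$value), , drop = FALSE]
  structure(list(
    with = scenario(prof, traj_w, "with_funder", unit$population_share),
    without = scenario(prof, traj_wo, "without_funder", unit$population_share),
    health_with = scenario(prof, traj_w, "with_funder", unit$population_share),
    health_without = scenario(prof, traj_hwo, "without_funder",
                              unit$population_share),
    meta = list(country_id = unit$country_id,
                geography_ids = unit$geography_ids,
                mode = mode, horizon = horizon,
                n_duplicate_fragments = n_dup,
                milestones = milestones)
  ), class = "scenario_pair")
}

#' Run the lives-saved analysis for one scenario pair
#'
#' Projects all four scenarios, takes annual differences, disaggregates
#' the family-planning from the direct-health impact, and attributes the
#' total to individual interventions.
#'
#' @param pair A `scenario_pair` from [assemble_scenarios()].
#' @param library An [intervention_library()].
#' @return A [lives_saved_result()].
#' @export
run_unit_analysis <- function(pair, library) {
  res_w <- run_projection(pair$with, library)
  res_wo <- run_projection(pair$without, library)
  res_hw <- run_projection(pair$health_with, library)
  res_hwo <- run_projection(pair$health_without, library)
  series <- decompose_fp_health(res_w, res_wo, res_hw, res_hwo)
  pi <- per_intervention_attribution(list(with = pair$with,
                                          without = pair$without), library)
  lives_saved_result(series, pi, country_id = pair$meta$country_id,
                     n_units = 1L)
}

#' Run the full analysis for one country
#'
#' Screens the country's register, groups eligible projects into analysis
#' units, assembles and runs the paired projections per unit, and sums the
#' unit results elementwise into the national estimate.
#'
#' @param register Register rows for one country.
#' @param profile The country's [country_profile()].
#' @param library An [intervention_library()].
#' @param mode `"achieved"` or `"forecast"`.
#' @param behaviour_conversion Message-exposure conversion factor.
#' @return A [lives_saved_result()] with attributes `screening` (the
#'   [screen_projects()] output) and `units` (the assembled pairs' meta).
#' @export
run_country_analysis <- function(register, profile, library,
                                 mode = c("achieved", "forecast"),
                                 behaviour_conversion = 1) {
  mode <- match.arg(mode)
  if (length(unique(register$country_id)) > 1)
    stop("register spans several countries; use aggregate_global()")
  screening <- screen_projects(register, library)
  if (nrow(screening$eligible) == 0) {
    yrs <- as.character(seq(profile$baseline_year + 1, profile$horizon_year))
    zero <- stats::setNames(rep(0, length(yrs)), yrs)
    out <- lives_saved_result(list(maternal_total = zero, maternal_fp = zero,
                                   maternal_health = zero,
                                   newborn_primary = zero,
                                   newborn_fertility = zero),
                              country_id = profile$country_id, n_units = 0L)
    attr(out, "screening") <- screening
    attr(out, "units") <- list()
    return(out)
  }
  units <- group_analysis_units(screening$eligible)
  pairs <- lapply(units, assemble_scenarios, profile = profile,
                  library = library, mode = mode,
                  behaviour_conversion = behaviour_conversion)
  results <- lapply(pairs, run_unit_analysis, library = library)
  out <- combine_results(results, country_id = profile$country_id)
  attr(out, "screening") <- screening
  attr(out, "units") <- lapply(pairs, `[[`, "meta")
  out
}

#' Aggregate national results into a global estimate
#'
#' @param country_results List of per-country [lives_saved_result()]s.
#' @return A [lives_saved_result()] labelled `"GLOBAL"`, with the input
#'   list retained in attribute `by_country`.
#' @export
aggregate_global <- function(country_results) {
  out <- combine_results(country_results, country_id = "GLOBAL")
  attr(out, "by_country") <- country_results
  out
}
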