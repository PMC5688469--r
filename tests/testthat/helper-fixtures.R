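# Fixtures built in code: a minimal single-cause country, a three-entry
# intervention library, and a register builder for hand-checkable cases.

tiny_profile <- function(nmr0 = 30, mmr0 = 300, cp0 = 0.1,
                         women = 700000, tfr0 = 5,
                         baseline_coverage = c(neonatal_care = 0.2)) {
  country_profile(
    country_id = "TINY",
    tfr0 = tfr0, women_reproductive_age = women,
    nmr0 = nmr0, mmr0 = mmr0,
    neonatal_cause_fractions = c(prematurity = 1),
    maternal_cause_fractions = c(haemorrhage = 1),
    baseline_coverage = baseline_coverage,
    cp0 = cp0, contraceptive_effectiveness = 0.9
  )
}

# neonatal_care: E=0.5 on prematurity; safe_birth: E=0.2 on haemorrhage;
# one family-planning entry with no direct effects.
tiny_library <- function() {
  intervention_library(
    intervention_spec("neonatal_care", "Essential newborn care",
                      period = "postnatal", category = "curative",
                      effects = data.frame(target_group = "neonatal",
                                           cause = "prematurity",
                                           effectiveness = 0.5,
                                           affected_fraction = 1)),
    intervention_spec("safe_birth", "Skilled birth attendance",
                      period = "childbirth", category = "preventive",
                      effects = data.frame(target_group = "maternal",
                                           cause = "haemorrhage",
                                           effectiveness = 0.2,
                                           affected_fraction = 1)),
    intervention_spec("fp_modern_methods", "Modern contraception",
                      period = "pre-pregnancy", category = "preventive",
                      is_family_planning = TRUE)
  )
}

# a flat trajectory at the profile's baseline over 2010..2015
flat_trajectory <- function(profile, ids = names(profile$baseline_coverage)) {
  years <- seq(profile$baseline_year, profile$horizon_year)
  cov <- matrix(rep(baseline_cov_for_test(profile, ids), length(years)),
                nrow = length(ids), ncol = length(years),
                dimnames = list(ids, years))
  cp <- stats::setNames(rep(profile$cp0, length(years)), years)
  coverage_trajectory(cov, cp)
}

baseline_cov_for_test <- function(profile, ids) {
  out <- stats::setNames(rep(0, length(ids)), ids)
  hit <- intersect(ids, names(profile$baseline_coverage))
  out[hit] <- profile$baseline_coverage[hit]
  out
}

# set one intervention's post-baseline coverage to a constant
with_coverage <- function(traj, id, value) {
  yrs <- colnames(traj$cov)[-1]
  traj$cov[id, yrs] <- value
  coverage_trajectory(traj$cov, traj$cp)
}

# one-project register rows: coverage-type entries for one intervention
simple_register <- function(project_id = "P1", country_id = "TINY",
                            intervention_id = "neonatal_care",
                            values = c(`2011` = 0.6, `2012` = 0.6,
                                       `2013` = 0.6, `2014` = 0.6,
                                       `2015` = 0.6),
                            provenance = "achieved",
                            attribution = 1, geography_id = "national",
                            population_share = 1,
                            management = "bilateral",
                            indicator_type = "coverage",
                            target_population = NA_real_) {
  yrs <- as.integer(names(values))
  tibble::tibble(
    project_id = project_id, country_id = country_id,
    management = management, start_year = min(yrs), end_year = max(yrs),
    total_funding = 1e6, attribution = attribution,
    geography_id = geography_id, population_share = population_share,
    intervention_id = intervention_id, indicator_type = indicator_type,
    year = yrs, value = unname(values),
    provenance = rep(provenance, length.out = length(yrs)),
    target_population = target_population
  )
}

# run the pipeline for every country of a generated register and return
# the global result
run_generated <- function(gen, mode = "forecast", behaviour_conversion = 1) {
  res <- lapply(names(gen$profiles), function(cid)
    run_country_analysis(gen$register[gen$register$country_id == cid, ],
                         gen$profiles[[cid]], gen$library, mode,
                         behaviour_conversion))
  names(res) <- names(gen$profiles)
  aggregate_global(res)
}

max_series_diff <- function(series_a, series_b) {
  max(mapply(function(a, b) {
    stopifnot(identical(names(a), names(b)))
    max(abs(a - b))
  }, series_a, series_b))
}
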