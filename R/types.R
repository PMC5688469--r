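#' Construct a country profile
#'
#' A country profile bundles the demographic and epidemiological baseline
#' needed to project births and cause-specific maternal and neonatal deaths:
#' total fertility, women of reproductive age, baseline neonatal mortality
#' rate (NMR, per 1000 live births) and maternal mortality ratio (MMR, per
#' 100,000 live births), cause-of-death fractions, baseline intervention
#' coverages and baseline contraceptive prevalence.
#'
#' @param country_id Country label.
#' @param tfr0 Baseline total fertility rate (births per woman).
#' @param women_reproductive_age Women of reproductive age. Either a single
#'   count held constant across the projection, or a named numeric vector
#'   keyed by calendar year covering every projection year.
#' @param nmr0 Baseline neonatal mortality rate per 1000 live births.
#' @param mmr0 Baseline maternal mortality ratio per 100,000 live births.
#' @param neonatal_cause_fractions,maternal_cause_fractions Named numeric
#'   vectors of cause-of-death fractions; each must sum to 1.
#' @param baseline_coverage Named numeric vector of baseline coverage (in
#'   `[0,1]`) per intervention id. Interventions absent from this vector are
#'   assumed to start at zero coverage.
#' @param cp0 Baseline contraceptive prevalence in `[0,1]`.
#' @param contraceptive_effectiveness Average use-effectiveness of
#'   contraception in `[0,1]` (default 0.9, the conventional value in the
#'   proximate-determinants literature).
#' @param baseline_year,horizon_year Calendar years bracketing the analysis
#'   (defaults 2010 and 2015).
#' @param mortality_source Label of the mortality estimate source the
#'   baseline rates come from (e.g. `"IGME"`, `"IHME"`, `"DHS"`).
#' @return An object of class `country_profile`.
#' @export
country_profile <- function(country_id,
                            tfr0,
                            women_reproductive_age,
                            nmr0,
                            mmr0,
                            neonatal_cause_fractions,
                            maternal_cause_fractions,
                            baseline_coverage = numeric(),
                            cp0 = 0,
                            contraceptive_effectiveness = 0.9,
                            baseline_year = 2010L,
                            horizon_year = 2015L,
                            mortality_source = "IGME") {
  profile <- structure(
    list(
      country_id = as.character(country_id),
      baseline_year = as.integer(baseline_year),
      horizon_year = as.integer(horizon_year),
      tfr0 = as.numeric(tfr0),
      women_reproductive_age = women_reproductive_age,
      nmr0 = as.numeric(nmr0),
      mmr0 = as.numeric(mmr0),
      neonatal_cause_fractions = unlist(neonatal_cause_fractions),
      maternal_cause_fractions = unlist(maternal_cause_fractions),
      baseline_coverage = unlist(baseline_coverage),
      cp0 = as.numeric(cp0),
      contraceptive_effectiveness = as.numeric(contraceptive_effectiveness),
      mortality_source = as.character(mortality_source)
    ),
    class = "country_profile"
  )
  validate_country_profile(profile)
}

#' @rdname country_profile
#' @param x Object to validate.
#' @export
validate_country_profile <- function(x) {
  stopifnot(inherits(x, "country_profile"))
  if (x$baseline_year >= x$horizon_year)
    stop("baseline_year must precede horizon_year")
  if (x$tfr0 < 0 || x$nmr0 < 0 || x$mmr0 < 0)
    stop("tfr0, nmr0 and mmr0 must be non-negative")
  for (nm in c("neonatal_cause_fractions", "maternal_cause_fractions")) {
    cf <- x[[nm]]
    if (length(cf) == 0 || is.null(names(cf)) || any(!nzchar(names(cf))))
      stop(nm, " must be a named numeric vector")
    if (any(cf < 0)) stop(nm, " must be non-negative")
    if (abs(sum(cf) - 1) > 1e-9)
      stop(nm, " must sum to 1 (got ", format(sum(cf), digits = 12), ")")
  }
  cov <- x$baseline_coverage
  if (length(cov) && (any(cov < 0) || any(cov > 1)))
    stop("baseline_coverage values must lie in [0,1]")
  if (x$cp0 < 0 || x$cp0 > 1) stop("cp0 must lie in [0,1]")
  if (x$contraceptive_effectiveness < 0 || x$contraceptive_effectiveness > 1)
    stop("contraceptive_effectiveness must lie in [0,1]")
  w <- x$women_reproductive_age
  if (any(w < 0)) stop("women_reproductive_age must be non-negative")
  x
}

#' @export
print.country_profile <- function(x, ...) {
  cat("<country_profile> ", x$country_id,
      " [", x$baseline_year, "-", x$horizon_year, "]\n", sep = "")
  cat("  TFR ", x$tfr0, ", NMR ", x$nmr0, "/1000, MMR ", x$mmr0,
      "/100k (", x$mortality_source, "), CP ", x$cp0, "\n", sep = "")
  cat("  causes: ", length(x$neonatal_cause_fractions), " neonatal / ",
      length(x$maternal_cause_fractions), " maternal; baseline coverages: ",
      length(x$baseline_coverage), "\n", sep = "")
  invisible(x)
}

# Women of reproductive age in a given year (scalar profiles are constant).
women_at <- function(profile, year) {
  w <- profile$women_reproductive_age
  if (length(w) == 1L && is.null(names(w))) return(as.numeric(w))
  key <- as.character(year)
  if (!key %in% names(w))
    stop("women_reproductive_age has no value for year ", year)
  as.numeric(w[[key]])
}

intervention_periods <- c("pre-pregnancy", "pregnancy", "childbirth", "postnatal")
intervention_categories <- c("preventive", "curative")

#' Construct an intervention specification
#'
#' Describes one health or family-planning intervention: where it sits on
#' the continuum of care, whether it is preventive or curative, and its
#' cause-specific effects. Each effect carries an effectiveness (the
#' proportional cause-specific mortality reduction at full coverage) and an
#' affected fraction (the share of that cause's deaths the intervention can
#' address), both in `[0,1]`.
#'
#' @param intervention_id Stable identifier.
#' @param name Human-readable name.
#' @param period One of `"pre-pregnancy"`, `"pregnancy"`, `"childbirth"`,
#'   `"postnatal"`.
#' @param category `"preventive"` or `"curative"`.
#' @param effects A data frame with columns `target_group` (`"neonatal"` or
#'   `"maternal"`), `cause`, `effectiveness`, and optionally
#'   `affected_fraction` (default 1).
#' @param is_family_planning If `TRUE` the intervention's coverage is
#'   interpreted as contraceptive prevalence and acts on fertility rather
#'   than through cause-specific effects; `effects` may then be empty.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(intervention_id, name = intervention_id,
                              period, category,
                              effects = NULL,
                              is_family_planning = FALSE) {
  period <- match.arg(period, intervention_periods)
  category <- match.arg(category, intervention_categories)
  if (is.null(effects)) {
    effects <- data.frame(target_group = character(), cause = character(),
                          effectiveness = numeric(),
                          affected_fraction = numeric(),
                          stringsAsFactors = FALSE)
  }
  effects <- as.data.frame(effects, stringsAsFactors = FALSE)
  if (!"affected_fraction" %in% names(effects))
    effects$affected_fraction <- rep(1, nrow(effects))
  effects$affected_fraction[is.na(effects$affected_fraction)] <- 1
  if (nrow(effects)) {
    bad <- effects$effectiveness < 0 | effects$effectiveness > 1 |
      effects$affected_fraction < 0 | effects$affected_fraction > 1
    if (any(bad))
      stop("effectiveness and affected_fraction must lie in [0,1]")
    if (!all(effects$target_group %in% c("neonatal", "maternal")))
      stop("effect target_group must be 'neonatal' or 'maternal'")
  } else if (!is_family_planning) {
    stop("an intervention needs at least one effect unless it is family planning")
  }
  structure(
    list(intervention_id = as.character(intervention_id),
         name = as.character(name),
         period = period, category = category,
         effects = effects,
         is_family_planning = isTRUE(is_family_planning)),
    class = "intervention_spec"
  )
}

#' Bundle intervention specifications into a library
#'
#' @param ... `intervention_spec` objects, or a single list of them.
#' @return A named list of class `intervention_library`, keyed by
#'   intervention id.
#' @export
intervention_library <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "intervention_spec"))
    specs <- specs[[1]]
  ok <- vapply(specs, inherits, logical(1), what = "intervention_spec")
  if (!all(ok)) stop("all elements must be intervention_spec objects")
  ids <- vapply(specs, `[[`, character(1), "intervention_id")
  if (anyDuplicated(ids)) stop("duplicate intervention ids in library")
  names(specs) <- ids
  structure(specs, class = "intervention_library")
}

#' @export
print.intervention_library <- function(x, ...) {
  cat("<intervention_library> ", length(x), " interventions\n", sep = "")
  for (s in x)
    cat(sprintf("  %-24s %-13s %-10s %s\n", s$intervention_id, s$period,
                s$category,
                if (s$is_family_planning) "family planning"
                else paste0(nrow(s$effects), " effect(s)")))
  invisible(x)
}

# ids of family-planning interventions in a library
fp_ids <- function(library) {
  names(library)[vapply(library, `[[`, logical(1), "is_family_planning")]
}

# canonical application order: continuum-of-care period, preventive first.
# The multiplicative residual makes results order-invariant; the order is
# retained for reporting.
library_order <- function(library) {
  p <- match(vapply(library, `[[`, character(1), "period"), intervention_periods)
  cc <- match(vapply(library, `[[`, character(1), "category"), intervention_categories)
  names(library)[order(p, cc, names(library))]
}

#' Construct a coverage trajectory
#'
#' Annual intervention coverages and contraceptive prevalence over the
#' projection window. The baseline-year column must carry the baseline
#' coverages so that projections are normalized to the 2010 situation.
#'
#' @param cov Numeric matrix of coverages in `[0,1]`; rownames are
#'   intervention ids, colnames are calendar years (baseline year included).
#' @param cp Named numeric vector of contraceptive prevalence in `[0,1]`,
#'   keyed by the same years.
#' @return An object of class `coverage_trajectory`.
#' @export
coverage_trajectory <- function(cov, cp) {
  cov <- as.matrix(cov)
  if (is.null(rownames(cov)) && nrow(cov) > 0)
    stop("cov must have intervention ids as rownames")
  if (is.null(colnames(cov)))
    stop("cov must have years as colnames")
  if (length(cov) && (any(cov < 0) || any(cov > 1)))
    stop("coverages must lie in [0,1]")
  if (any(cp < 0) || any(cp > 1))
    stop("contraceptive prevalence must lie in [0,1]")
  if (!setequal(names(cp), colnames(cov)))
    stop("cp must cover exactly the trajectory years")
  cp <- cp[colnames(cov)]
  structure(list(cov = cov, cp = cp, years = as.integer(colnames(cov))),
            class = "coverage_trajectory")
}

#' Construct a projection scenario
#'
#' Binds a country profile to a coverage trajectory for one member of a
#' with/without-funder pair.
#'
#' @param profile A [country_profile()].
#' @param trajectory A [coverage_trajectory()].
#' @param label `"with_funder"` or `"without_funder"`.
#' @param population_share Share of national births the analysis unit
#'   covers, in `(0,1]` (1 for national programmes).
#' @return An object of class `scenario`.
#' @export
scenario <- function(profile, trajectory,
                     label = c("with_funder", "without_funder"),
                     population_share = 1) {
  label <- match.arg(label)
  stopifnot(inherits(profile, "country_profile"),
            inherits(trajectory, "coverage_trajectory"))
  if (population_share <= 0 || population_share > 1)
    stop("population_share must lie in (0,1]")
  base <- as.character(profile$baseline_year)
  if (!base %in% colnames(trajectory$cov))
    stop("trajectory must include the baseline year ", base)
  cov0 <- baseline_cov_for(profile, rownames(trajectory$cov))
  if (length(cov0) && any(abs(trajectory$cov[, base] - cov0) > 1e-9))
    stop("baseline-year coverages must equal the profile's baseline coverage")
  if (abs(trajectory$cp[[base]] - profile$cp0) > 1e-9)
    stop("baseline-year contraceptive prevalence must equal cp0")
  structure(list(profile = profile, trajectory = trajectory, label = label,
                 population_share = population_share),
            class = "scenario")
}

# baseline coverage vector for a set of intervention ids (0 when absent,
# cp0 never substituted here: family-planning baselines are handled by the
# protocol when it builds trajectories).
baseline_cov_for <- function(profile, ids) {
  out <- stats::setNames(rep(0, length(ids)), ids)
  hit <- intersect(ids, names(profile$baseline_coverage))
  out[hit] <- profile$baseline_coverage[hit]
  out
}
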