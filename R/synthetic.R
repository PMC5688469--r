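# Synthetic study data: country profiles, an intervention library and a
# project register with the template's heterogeneity (coverage vs
# services-delivered vs commodity vs message-exposure indicators, achieved
# vs forecast values, national vs subnational geographies, overlapping
# projects, unmodelable and centrally managed projects), all with known
# construction metadata so tests can check the bookkeeping.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

neonatal_causes_all <- c("prematurity", "birth_asphyxia", "neonatal_sepsis",
                         "neonatal_pneumonia", "congenital",
                         "neonatal_tetanus")
maternal_causes_all <- c("haemorrhage", "hypertensive_disorders",
                         "maternal_sepsis", "obstructed_labour",
                         "abortion_complications", "indirect_causes")

default_profile_params <- function() {
  list(nmr_range = c(15, 60), mmr_range = c(100, 900), tfr_range = c(2, 7),
       n_causes_range = c(3, 6), cp0_range = c(0.05, 0.45),
       women_range = c(3e5, 3e6), baseline_cov_range = c(0.1, 0.6),
       intervention_ids = character())
}

#' Generate a synthetic country profile
#'
#' Draws a plausible low/middle-income baseline: NMR 15-60 per 1000, MMR
#' 100-900 per 100,000, TFR 2-7, 3-6 causes of death per group with
#' Dirichlet-distributed fractions, and baseline coverages for the
#' supplied intervention ids. Reproducible per seed.
#'
#' @param seed Integer seed.
#' @param params Optional list overriding any of the default ranges
#'   (`nmr_range`, `mmr_range`, `tfr_range`, `n_causes_range`,
#'   `cp0_range`, `women_range`, `baseline_cov_range`,
#'   `intervention_ids`). Ranges outside the documented bounds are
#'   rejected.
#' @param country_id Country label.
#' @return A [country_profile()].
#' @export
make_country_profile <- function(seed, params = list(),
                                 country_id = sprintf("SYN%03d", seed %% 1000)) {
  p <- utils::modifyList(default_profile_params(), params)
  check_range <- function(r, lo, hi, nm) {
    if (r[1] < lo || r[2] > hi || r[1] > r[2])
      stop(nm, " must lie within [", lo, ",", hi, "]")
  }
  check_range(p$nmr_range, 15, 60, "nmr_range")
  check_range(p$mmr_range, 100, 900, "mmr_range")
  check_range(p$tfr_range, 2, 7, "tfr_range")
  check_range(p$n_causes_range, 3, 6, "n_causes_range")
  with_seed(seed, {
    nn <- sample(seq(p$n_causes_range[1], p$n_causes_range[2]), 1)
    nm <- sample(seq(p$n_causes_range[1], p$n_causes_range[2]), 1)
    dirichlet <- function(k) { x <- stats::rgamma(k, shape = 1); x / sum(x) }
    ncf <- stats::setNames(dirichlet(nn), neonatal_causes_all[seq_len(nn)])
    mcf <- stats::setNames(dirichlet(nm), maternal_causes_all[seq_len(nm)])
    cov0 <- stats::setNames(
      stats::runif(length(p$intervention_ids),
                   p$baseline_cov_range[1], p$baseline_cov_range[2]),
      p$intervention_ids)
    country_profile(
      country_id = country_id,
      tfr0 = stats::runif(1, p$tfr_range[1], p$tfr_range[2]),
      women_reproductive_age = round(stats::runif(1, p$women_range[1],
                                                  p$women_range[2])),
      nmr0 = stats::runif(1, p$nmr_range[1], p$nmr_range[2]),
      mmr0 = stats::runif(1, p$mmr_range[1], p$mmr_range[2]),
      neonatal_cause_fractions = ncf,
      maternal_cause_fractions = mcf,
      baseline_coverage = cov0,
      cp0 = stats::runif(1, p$cp0_range[1], p$cp0_range[2])
    )
  })
}

#' Generate a synthetic intervention library
#'
#' Between 9 and 15 interventions covering all four continuum-of-care
#' periods and both preventive/curative categories, including exactly one
#' family-planning intervention. Effectiveness values are drawn in
#' `[0.05, 0.95]` and affected fractions in `[0.5, 1]`; effect causes are
#' drawn from the leading causes so every generated profile carries them.
#'
#' @param seed Integer seed.
#' @return An [intervention_library()].
#' @export
make_intervention_library <- function(seed) {
  with_seed(seed, {
    n <- sample(9:15, 1)
    combos <- expand.grid(period = intervention_periods,
                          category = intervention_categories,
                          stringsAsFactors = FALSE)
    specs <- list(intervention_spec(
      "fp_modern_methods", "Modern contraceptive methods",
      period = "pre-pregnancy", category = "preventive",
      is_family_planning = TRUE))
    for (i in seq_len(n - 1)) {
      combo <- combos[(i - 1) %% nrow(combos) + 1, ]
      k <- sample(1:2, 1)
      eff <- do.call(rbind, lapply(seq_len(k), function(j) {
        tg <- sample(c("neonatal", "maternal"), 1)
        cause <- sample(if (tg == "neonatal") neonatal_causes_all[1:3]
                        else maternal_causes_all[1:3], 1)
        data.frame(target_group = tg, cause = cause,
                   effectiveness = stats::runif(1, 0.05, 0.95),
                   affected_fraction = stats::runif(1, 0.5, 1),
                   stringsAsFactors = FALSE)
      }))
      specs[[i + 1]] <- intervention_spec(
        sprintf("intv_%02d", i), sprintf("Intervention %02d", i),
        period = combo$period, category = combo$category, effects = eff)
    }
    intervention_library(specs)
  })
}

default_register_params <- function() {
  list(frac_multilateral = 0.10, frac_unmodelable = 0.10,
       frac_no_data = 0.05, p_subnational = 0.3, subnational_share = 0.4,
       n_duplicate_pairs = 2, attribution_range = c(0.2, 0.8),
       gain_range = c(0.05, 0.3), achieved_through_range = c(2012, 2014),
       p_fp_project = 0.5, indicator_mix = c(coverage = 0.5,
                                             services_delivered = 0.2,
                                             commodities = 0.15,
                                             message_exposure = 0.1,
                                             milestone = 0.05))
}

#' Generate a synthetic project register with known construction
#'
#' Emulates the country-office reporting template: per-project funding,
#' attribution and geography, and per-intervention annual indicator values
#' flagged achieved or forecast. Injects known numbers of centrally
#' managed/multilateral projects, unmodelable projects (interventions
#' outside the library), projects with no data, duplicated reporting of a
#' single activity, and subnational geographies, and records them all in
#' the metadata so the pipeline's screening and de-duplication can be
#' checked against the construction.
#'
#' @param seed Integer seed.
#' @param n_countries Number of countries.
#' @param n_projects Total number of projects (including the injected
#'   excluded ones).
#' @param params Optional overrides of the default injection fractions and
#'   value-path parameters (see `default_register_params`).
#' @return A list: `register` (tibble), `profiles` (named list of
#'   [country_profile()]s), `library`, and `meta` (construction
#'   bookkeeping: `n_multilateral`, `n_unmodelable`, `n_no_data`,
#'   `n_eligible`, `n_duplicate_fragments` — every overlapping
#'   (geography, intervention, year) fragment the merge step will
#'   collapse, whether injected or emerging from independently sampled
#'   projects — `geographies_per_country`, `achieved_through`).
#' @export
make_project_register <- function(seed, n_countries = 3, n_projects = 12,
                                  params = list()) {
  p <- utils::modifyList(default_register_params(), params)
  n_multi <- round(p$frac_multilateral * n_projects)
  n_unmod <- round(p$frac_unmodelable * n_projects)
  n_nodata <- round(p$frac_no_data * n_projects)
  n_excl <- n_multi + n_unmod + n_nodata
  if (n_projects - n_excl < n_countries)
    stop("infeasible params: fewer eligible projects than countries")
  library <- make_intervention_library(seed + 1)
  fp <- fp_ids(library)
  health_ids <- setdiff(names(library), fp)

  with_seed(seed, {
    profiles <- list()
    for (i in seq_len(n_countries)) {
      cid <- sprintf("C%02d", i)
      profiles[[cid]] <- make_country_profile(
        seed + 100 + i, list(intervention_ids = names(library)),
        country_id = cid)
    }
    years <- 2011:2015
    rows <- list()
    achieved_through <- integer()

    add_rows <- function(pid, cid, management, geography, share, attr,
                         iid, type, path, prov_by_year, target_pop) {
      tibble::tibble(
        project_id = pid, country_id = cid, management = management,
        start_year = 2011L, end_year = 2015L,
        total_funding = round(stats::runif(1, 1e6, 5e7)),
        attribution = attr, geography_id = geography,
        population_share = share, intervention_id = iid,
        indicator_type = type, year = years, value = path,
        provenance = prov_by_year, target_population = target_pop)
    }

    cids <- sprintf("C%02d", seq_len(n_countries))
    roles <- c(rep("multilateral", n_multi), rep("unmodelable", n_unmod),
               rep("no_data", n_nodata),
               rep("eligible", n_projects - n_excl))
    assigned_cids <- rep(cids, length.out = n_projects)
    # fragments bookkeeping for duplicate injection: eligible project rows
    frag_index <- list()

    for (j in seq_len(n_projects)) {
      pid <- sprintf("P%03d", j)
      cid <- assigned_cids[j]
      prof <- profiles[[cid]]
      role <- roles[j]
      management <- if (role == "multilateral")
        sample(c("central_multicountry", "multilateral"), 1) else "bilateral"
      subnat <- stats::runif(1) < p$p_subnational
      geography <- if (subnat) paste0("region_", cid) else "national"
      share <- if (subnat) p$subnational_share else 1
      attrf <- round(stats::runif(1, p$attribution_range[1],
                                  p$attribution_range[2]), 2)
      ach_to <- sample(seq(p$achieved_through_range[1],
                           p$achieved_through_range[2]), 1)
      achieved_through[[pid]] <- ach_to
      prov <- ifelse(years <= ach_to, "achieved", "forecast")

      n_int <- sample(1:3, 1)
      iids <- sample(health_ids, n_int)
      if (stats::runif(1) < p$p_fp_project) iids <- c(iids, fp[1])
      if (role == "unmodelable")
        iids <- paste0("training_programme_", seq_along(iids))

      has_coverage_entry <- FALSE
      for (iid in iids) {
        is_fp <- iid %in% fp
        cov0 <- if (is_fp) prof$cp0
          else if (iid %in% names(prof$baseline_coverage))
            unname(prof$baseline_coverage[[iid]]) else 0.3
        gain <- stats::runif(1, p$gain_range[1], p$gain_range[2])
        cov_path <- pmin(cov0 + gain * (years - 2010) / 5, 1)
        type <- if (is_fp || role == "unmodelable") "coverage"
          else sample(names(p$indicator_mix), 1, prob = p$indicator_mix)
        # every eligible project carries at least one coverage-bearing
        # entry so its analysis unit has usable years
        if (type == "milestone" && !has_coverage_entry &&
            iid == iids[length(iids)])
          type <- "coverage"
        if (type != "milestone") has_coverage_entry <- TRUE
        if (role == "no_data") {
          rows[[length(rows) + 1L]] <- add_rows(
            pid, cid, management, geography, share, attrf, iid,
            "coverage", rep(NA_real_, length(years)), prov, NA_real_)
          next
        }
        if (type == "coverage") {
          path <- cov_path; tp <- NA_real_
        } else if (type == "milestone") {
          path <- ifelse(years == min(years), 1, NA_real_); tp <- NA_real_
        } else {
          tp <- round(stats::runif(1, 5e4, 5e5))
          path <- round(cov_path * tp)
        }
        rows[[length(rows) + 1L]] <- add_rows(
          pid, cid, management, geography, share, attrf, iid, type, path,
          prov, tp)
        if (role == "eligible" && type != "milestone" && !is_fp)
          frag_index[[length(frag_index) + 1L]] <- list(
            pid = pid, cid = cid, geography = geography, share = share,
            iid = iid, coverage = cov_path, prov = prov)
      }
    }

    # duplicate reporting: re-report an existing activity from a second
    # project in the same country and geography, at 80% of the coverage
    for (d in seq_len(p$n_duplicate_pairs)) {
      if (length(frag_index) == 0) break
      src <- frag_index[[sample(length(frag_index), 1)]]
      host <- sprintf("PDUP%02d", d)
      rows[[length(rows) + 1L]] <- add_rows(
        host, src$cid, "bilateral", src$geography, src$share,
        round(stats::runif(1, p$attribution_range[1],
                           p$attribution_range[2]), 2),
        src$iid, "coverage", pmin(src$coverage * 0.8, 1), src$prov,
        NA_real_)
      achieved_through[[host]] <- max(years[src$prov == "achieved"])
    }

    register <- validate_register(dplyr::bind_rows(rows))
    eligible_pids <- unique(register$project_id[
      register$management == "bilateral" &
        register$intervention_id %in% names(library) &
        !is.na(register$value)])
    geo <- unique(as.data.frame(
      register[register$project_id %in% eligible_pids,
               c("country_id", "geography_id")]))
    geographies_per_country <- table(geo$country_id)
    # overlapping fragments the de-duplication step will collapse: any
    # (country, geography, intervention, year) reported by more than one
    # eligible project, whether injected deliberately or arising from
    # independent projects reporting the same activity
    fr <- unique(as.data.frame(register[
      register$project_id %in% eligible_pids &
        register$intervention_id %in% names(library) &
        register$indicator_type != "milestone" & !is.na(register$value),
      c("project_id", "country_id", "geography_id", "intervention_id",
        "year")]))
    cell <- table(paste(fr$country_id, fr$geography_id,
                        fr$intervention_id, fr$year))
    meta_dup <- sum(cell - 1L)

    list(register = register, profiles = profiles, library = library,
         meta = list(seed = seed,
                     n_projects = n_projects,
                     n_multilateral = n_multi,
                     n_unmodelable = n_unmod,
                     n_no_data = n_nodata,
                     n_eligible = n_projects - n_excl + p$n_duplicate_pairs *
                       (length(frag_index) > 0),
                     n_duplicate_fragments = meta_dup,
                     geographies_per_country = geographies_per_country,
                     achieved_through = achieved_through))
  })
}

#' Per-birth Monte-Carlo microsimulation oracle
#'
#' An independent stochastic check on the deterministic engine. For each
#' simulated birth and cause, a potential death is drawn at the baseline
#' cause-specific risk; each intervention effect matching that cause then
#' independently reaches the birth with probability equal to its coverage
#' and, if it does, averts the death with probability
#' effectiveness x affected fraction. Simulated deaths are normalized by
#' the same baseline-residual denominator as the engine and rescaled from
#' the simulated cohort to the scenario's projected births. Standard
#' errors are binomial.
#'
#' @param scn A [scenario()].
#' @param library An [intervention_library()].
#' @param n_births_per_year Simulated cohort size per year (>= 1).
#' @param seed Integer seed.
#' @return A list with `births` (expected births per year),
#'   `neonatal_deaths`, `maternal_deaths`, `neonatal_se`, `maternal_se`
#'   (cause-by-year matrices), and `years`.
#' @export
microsim_oracle <- function(scn, library, n_births_per_year = 2e5,
                            seed = 1L) {
  stopifnot(n_births_per_year >= 1)
  profile <- scn$profile
  traj <- scn$trajectory
  years <- traj$years
  ykey <- as.character(years)
  e <- profile$contraceptive_effectiveness
  # independent re-derivation of expected births (no engine code)
  f <- function(u) 1 - 1.08 * u * e
  births <- vapply(years, function(y) {
    w <- profile$women_reproductive_age
    w <- if (length(w) == 1L && is.null(names(w))) w else w[[as.character(y)]]
    w * (profile$tfr0 / 35) * f(traj$cp[[as.character(y)]]) /
      f(profile$cp0) * scn$population_share
  }, numeric(1))
  names(births) <- ykey

  ids <- rownames(traj$cov)
  cov0 <- vapply(ids, function(id)
    if (id %in% names(profile$baseline_coverage))
      unname(profile$baseline_coverage[[id]]) else 0, numeric(1))
  names(cov0) <- ids
  n <- as.integer(n_births_per_year)

  sim_group <- function(rate, fractions, grp) {
    dm <- matrix(0, length(fractions), length(years),
                 dimnames = list(names(fractions), ykey))
    se <- dm
    for (cause in names(fractions)) {
      # baseline residual denominator, identical to the engine's
      rf0 <- 1
      for (id in ids) {
        eff <- library[[id]]$effects
        hit <- eff$target_group == grp & eff$cause == cause
        if (any(hit))
          rf0 <- rf0 * prod(1 - eff$effectiveness[hit] *
                              eff$affected_fraction[hit] * cov0[[id]])
      }
      for (y in ykey) {
        at_risk <- stats::rbinom(1, n, rate * fractions[[cause]])
        for (id in ids) {
          eff <- library[[id]]$effects
          hit <- which(eff$target_group == grp & eff$cause == cause)
          for (k in hit) {
            averted <- stats::rbinom(1, at_risk,
                                     eff$effectiveness[k] *
                                       eff$affected_fraction[k] *
                                       traj$cov[id, y])
            at_risk <- at_risk - averted
          }
        }
        p_hat <- at_risk / n
        p_se <- (at_risk + 0.5) / (n + 1)
        dm[cause, y] <- births[[y]] * p_hat / rf0
        se[cause, y] <- births[[y]] * sqrt(p_se * (1 - p_se) / n) / rf0
      }
    }
    list(deaths = dm, se = se)
  }

  with_seed(seed, {
    nn <- sim_group(profile$nmr0 / 1000, profile$neonatal_cause_fractions,
                    "neonatal")
    mm <- sim_group(profile$mmr0 / 1e5, profile$maternal_cause_fractions,
                    "maternal")
    list(births = births,
         neonatal_deaths = nn$deaths, neonatal_se = nn$se,
         maternal_deaths = mm$deaths, maternal_se = mm$se,
         years = years)
  })
}
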