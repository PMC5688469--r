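#' Independent closed-form recomputation of expected lives saved
#'
#' Re-derives the expected lives-saved series for a register by direct
#' brute-force evaluation of the model formulas — screening, geographic
#' grouping, indicator conversion, achieved/forecast resolution,
#' per-project counterfactual, merge-by-maximum, Bongaarts-scaled births,
#' multiplicative residual mortality, pairwise differencing, the
#' family-planning/direct-health decomposition and log-residual
#' attribution — in plain loops that share no code with the cohort engine
#' or the protocol layer. Serves as the exactness target for pipeline
#' equality tests on synthetic registers.
#'
#' @param register Project-register tibble.
#' @param profiles Named list of [country_profile()]s keyed by country id.
#' @param library An [intervention_library()].
#' @param mode `"achieved"` or `"forecast"`.
#' @param behaviour_conversion Message-exposure conversion factor.
#' @return A list of class `synthetic_truth`: `by_country` (named list of
#'   per-country series/totals/per_intervention) and `global`.
#' @export
closed_form_truth <- function(register, profiles, library,
                              mode = c("achieved", "forecast"),
                              behaviour_conversion = 1) {
  mode <- match.arg(mode)
  lib_ids <- names(library)
  is_fp_id <- vapply(library, function(s) s$is_family_planning, logical(1))
  fp_set <- lib_ids[is_fp_id]

  country_truth <- function(cid) {
    prof <- profiles[[cid]]
    rows <- register[register$country_id == cid, , drop = FALSE]
    e <- prof$contraceptive_effectiveness
    fidx <- function(u) 1 - 1.08 * u * e

    # --- screening, re-derived ---
    keep <- character()
    for (pid in unique(rows$project_id)) {
      pr <- rows[rows$project_id == pid, , drop = FALSE]
      if (pr$management[1] != "bilateral") next
      lm <- pr$intervention_id %in% lib_ids
      if (!any(lm)) next
      if (all(is.na(pr$value[lm]))) next
      keep <- c(keep, pid)
    }
    rows <- rows[rows$project_id %in% keep, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)

    base_cov <- function(iid) {
      if (iid %in% fp_set) return(prof$cp0)
      if (iid %in% names(prof$baseline_coverage))
        return(unname(prof$baseline_coverage[[iid]]))
      0
    }

    unit_results <- list()
    for (gid in sort(unique(rows$geography_id))) {
      ur <- rows[rows$geography_id == gid, , drop = FALSE]
      share <- if (gid == "national") 1 else ur$population_share[1]

      # --- resolve + convert + counterfactual, per fragment ---
      frags <- list()
      ur2 <- ur[ur$intervention_id %in% lib_ids &
                  ur$indicator_type != "milestone" & !is.na(ur$value), ,
                drop = FALSE]
      if (nrow(ur2)) {
        for (pid in unique(ur2$project_id)) {
          for (iid in unique(ur2$intervention_id[ur2$project_id == pid])) {
            sub <- ur2[ur2$project_id == pid & ur2$intervention_id == iid, ,
                       drop = FALSE]
            for (y in unique(sub$year)) {
              sy <- sub[sub$year == y, , drop = FALSE]
              ach <- sy[sy$provenance == "achieved", , drop = FALSE]
              pick <- if (nrow(ach)) ach else sy
              pick <- pick[which.max(pick$value), , drop = FALSE]
              v <- pick$value
              cvg <- switch(pick$indicator_type,
                coverage = v,
                services_delivered = min(v / pick$target_population, 1),
                commodities = min(v / pick$target_population, 1),
                message_exposure = min(v / pick$target_population *
                                         behaviour_conversion, 1))
              c0 <- base_cov(iid)
              frags[[length(frags) + 1L]] <- list(
                iid = iid, year = y,
                w = cvg,
                wo = c0 + (1 - pick$attribution) * (cvg - c0),
                prov = if (nrow(ach)) "achieved" else "forecast")
            }
          }
        }
      }
      fy <- vapply(frags, function(f) f$year, numeric(1))
      fprov <- vapply(frags, function(f) f$prov, character(1))
      horizon <- if (mode == "forecast") prof$horizon_year else {
        ay <- fy[fprov == "achieved"]
        if (length(ay) == 0)
          stop("analysis unit has zero usable years in achieved mode")
        min(max(ay), prof$horizon_year)
      }
      yrs <- seq(prof$baseline_year + 1, horizon)

      ids <- sort(unique(vapply(frags, function(f) f$iid, character(1))))
      cw <- cwo <- list()
      for (iid in ids) {
        cw[[iid]] <- cwo[[iid]] <- stats::setNames(
          rep(base_cov(iid), length(yrs) + 1),
          c(prof$baseline_year, yrs))
        for (y in yrs) {
          sel <- vapply(frags, function(f) f$iid == iid && f$year == y,
                        logical(1))
          if (any(sel)) {
            cw[[iid]][[as.character(y)]] <-
              max(vapply(frags[sel], function(f) f$w, numeric(1)))
            cwo[[iid]][[as.character(y)]] <-
              max(vapply(frags[sel], function(f) f$wo, numeric(1)))
          }
        }
      }
      allyrs <- c(prof$baseline_year, yrs)
      cp_w <- cp_wo <- stats::setNames(rep(prof$cp0, length(allyrs)),
                                       allyrs)
      ufp <- intersect(ids, fp_set)
      if (length(ufp)) {
        for (y in yrs) {
          cp_w[[as.character(y)]] <-
            max(vapply(ufp, function(i) cw[[i]][[as.character(y)]],
                       numeric(1)))
          cp_wo[[as.character(y)]] <-
            max(vapply(ufp, function(i) cwo[[i]][[as.character(y)]],
                       numeric(1)))
        }
      }

      births_of <- function(cp, y) {
        w <- prof$women_reproductive_age
        w <- if (length(w) == 1L && is.null(names(w))) w
          else w[[as.character(y)]]
        w * (prof$tfr0 / 35) * fidx(cp[[as.character(y)]]) /
          fidx(prof$cp0) * share
      }
      resid <- function(covs, grp, cause, y) {
        r <- 1
        for (iid in ids) {
          eff <- library[[iid]]$effects
          for (k in seq_len(nrow(eff))) {
            if (eff$target_group[k] == grp && eff$cause[k] == cause)
              r <- r * (1 - eff$effectiveness[k] * eff$affected_fraction[k] *
                          covs[[iid]][[as.character(y)]])
          }
        }
        r
      }
      resid0 <- function(grp, cause) {
        r <- 1
        for (iid in ids) {
          eff <- library[[iid]]$effects
          for (k in seq_len(nrow(eff))) {
            if (eff$target_group[k] == grp && eff$cause[k] == cause)
              r <- r * (1 - eff$effectiveness[k] * eff$affected_fraction[k] *
                          base_cov(iid))
          }
        }
        r
      }
      deaths <- function(covs, cp, grp, y) {
        rate <- if (grp == "neonatal") prof$nmr0 / 1000 else prof$mmr0 / 1e5
        fr <- if (grp == "neonatal") prof$neonatal_cause_fractions
          else prof$maternal_cause_fractions
        b <- births_of(cp, y)
        tot <- 0
        for (cause in names(fr))
          tot <- tot + b * rate * fr[[cause]] *
            resid(covs, grp, cause, y) / resid0(grp, cause)
        tot
      }

      ykey <- as.character(yrs)
      z <- stats::setNames(rep(0, length(yrs)), ykey)
      s <- list(maternal_total = z, maternal_fp = z, maternal_health = z,
                newborn_primary = z, newborn_fertility = z)
      for (y in yrs) {
        k <- as.character(y)
        m_w <- deaths(cw, cp_w, "maternal", y)
        m_wo <- deaths(cwo, cp_wo, "maternal", y)
        m_hwo <- deaths(cwo, cp_w, "maternal", y)
        n_w <- deaths(cw, cp_w, "neonatal", y)
        n_wo <- deaths(cwo, cp_wo, "neonatal", y)
        n_hwo <- deaths(cwo, cp_w, "neonatal", y)
        s$maternal_total[[k]] <- m_wo - m_w
        s$maternal_health[[k]] <- m_hwo - m_w
        s$maternal_fp[[k]] <- (m_wo - m_w) - (m_hwo - m_w)
        s$newborn_primary[[k]] <- n_hwo - n_w
        s$newborn_fertility[[k]] <- (n_wo - n_w) - (n_hwo - n_w)
      }

      # --- per-intervention attribution, re-derived ---
      pi <- stats::setNames(rep(0, length(ids)), ids)
      for (grp in c("neonatal", "maternal")) {
        rate <- if (grp == "neonatal") prof$nmr0 / 1000 else prof$mmr0 / 1e5
        fr <- if (grp == "neonatal") prof$neonatal_cause_fractions
          else prof$maternal_cause_fractions
        for (y in yrs) {
          b_w <- births_of(cp_w, y)
          b_wo <- births_of(cp_wo, y)
          for (cause in names(fr)) {
            r0 <- resid0(grp, cause)
            rr_w <- rate * fr[[cause]] * resid(cw, grp, cause, y) / r0
            rr_wo <- rate * fr[[cause]] * resid(cwo, grp, cause, y) / r0
            health_part <- b_w * (rr_wo - rr_w)
            fert_part <- (b_wo - b_w) * rr_wo
            if (health_part != 0) {
              w <- stats::setNames(rep(0, length(ids)), ids)
              for (iid in ids) {
                eff <- library[[iid]]$effects
                for (k in seq_len(nrow(eff))) {
                  if (eff$target_group[k] == grp && eff$cause[k] == cause) {
                    ea <- eff$effectiveness[k] * eff$affected_fraction[k]
                    w[[iid]] <- w[[iid]] +
                      log1p(-ea * cwo[[iid]][[as.character(y)]]) -
                      log1p(-ea * cw[[iid]][[as.character(y)]])
                  }
                }
              }
              if (sum(w) != 0) pi <- pi + health_part * w / sum(w)
            }
            if (fert_part != 0 && length(ufp)) {
              dcp <- vapply(ufp, function(i)
                cw[[i]][[as.character(y)]] - cwo[[i]][[as.character(y)]],
                numeric(1))
              wfp <- if (sum(dcp) != 0) dcp / sum(dcp)
                else rep(1 / length(ufp), length(ufp))
              pi[ufp] <- pi[ufp] + fert_part * wfp
            }
          }
        }
      }
      unit_results[[length(unit_results) + 1L]] <-
        list(series = s, per_intervention = pi)
    }

    # --- sum units on the union of years ---
    all_y <- sort(unique(unlist(lapply(unit_results, function(u)
      as.integer(names(u$series$maternal_total))))))
    key <- as.character(all_y)
    z <- stats::setNames(rep(0, length(key)), key)
    s <- list(maternal_total = z, maternal_fp = z, maternal_health = z,
              newborn_primary = z, newborn_fertility = z)
    pi_all <- numeric()
    for (u in unit_results) {
      for (nm in names(s))
        s[[nm]][names(u$series[[nm]])] <-
          s[[nm]][names(u$series[[nm]])] + u$series[[nm]]
      for (iid in names(u$per_intervention)) {
        if (!iid %in% names(pi_all)) pi_all[[iid]] <- 0
        pi_all[[iid]] <- pi_all[[iid]] + u$per_intervention[[iid]]
      }
    }
    list(series = s, per_intervention = pi_all[sort(names(pi_all))],
         totals = vapply(s, sum, numeric(1)), n_units = length(unit_results))
  }

  by_country <- list()
  for (cid in names(profiles)) {
    ct <- country_truth(cid)
    if (!is.null(ct)) by_country[[cid]] <- ct
  }
  gy <- sort(unique(unlist(lapply(by_country, function(ct)
    as.integer(names(ct$series$maternal_total))))))
  key <- as.character(gy)
  z <- stats::setNames(rep(0, length(key)), key)
  gs <- list(maternal_total = z, maternal_fp = z, maternal_health = z,
             newborn_primary = z, newborn_fertility = z)
  gpi <- numeric()
  for (ct in by_country) {
    for (nm in names(gs))
      gs[[nm]][names(ct$series[[nm]])] <-
        gs[[nm]][names(ct$series[[nm]])] + ct$series[[nm]]
    for (iid in names(ct$per_intervention)) {
      if (!iid %in% names(gpi)) gpi[[iid]] <- 0
      gpi[[iid]] <- gpi[[iid]] + ct$per_intervention[[iid]]
    }
  }
  structure(list(by_country = by_country,
                 global = list(series = gs,
                               per_intervention = gpi[sort(names(gpi))],
                               totals = vapply(gs, sum, numeric(1)))),
            class = "synthetic_truth")
}
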