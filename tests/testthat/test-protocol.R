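test_that("screening partitions the register and labels exclusion reasons", {
  lib <- tiny_library()
  reg <- dplyr::bind_rows(
    simple_register("P1"),
    simple_register("P2", management = "multilateral"),
    simple_register("P3", intervention_id = "training_programme"),
    simple_register("P4", values = c(`2011` = NA, `2012` = NA))
  )
  scr <- screen_projects(reg, lib)
  expect_setequal(unique(scr$eligible$project_id), "P1")
  expect_equal(nrow(scr$excluded), 3)
  expect_equal(scr$excluded$reason[scr$excluded$project_id == "P2"],
               "central/multilateral")
  expect_equal(scr$excluded$reason[scr$excluded$project_id == "P3"],
               "not modelable")
  expect_equal(scr$excluded$reason[scr$excluded$project_id == "P4"],
               "no data")
  # every project lands in exactly one list
  expect_equal(length(unique(scr$eligible$project_id)) + nrow(scr$excluded),
               length(unique(reg$project_id)))
})

test_that("screening recovers the generator's injected exclusion counts", {
  gen <- make_project_register(11, n_countries = 2, n_projects = 20,
                               params = list(frac_multilateral = 0.15,
                                             frac_unmodelable = 0.20,
                                             frac_no_data = 0.10))
  scr <- screen_projects(gen$register, gen$library)
  reasons <- table(scr$excluded$reason)
  expect_equal(unname(reasons[["central/multilateral"]]),
               gen$meta$n_multilateral)
  expect_equal(unname(reasons[["not modelable"]]), gen$meta$n_unmodelable)
  expect_equal(unname(reasons[["no data"]]), gen$meta$n_no_data)
  expect_equal(length(unique(scr$eligible$project_id)), gen$meta$n_eligible)
})

test_that("analysis units group by country and geography", {
  lib <- tiny_library()
  reg <- dplyr::bind_rows(
    simple_register("P1", geography_id = "national"),
    simple_register("P2", geography_id = "national"),
    simple_register("P3", country_id = "OTHER", geography_id = "north",
                    population_share = 0.3),
    simple_register("P4", country_id = "OTHER", geography_id = "south",
                    population_share = 0.5)
  )
  units <- group_analysis_units(screen_projects(reg, lib)$eligible)
  expect_equal(length(units), 3)  # one national + two disjoint subnational
  nat <- units[[which(vapply(units, function(u) u$country_id == "TINY",
                             logical(1)))]]
  expect_equal(nat$population_share, 1)
  expect_setequal(unique(nat$entries$project_id), c("P1", "P2"))
  # conflicting shares for one geography are rejected
  bad <- dplyr::bind_rows(
    simple_register("P5", geography_id = "north", population_share = 0.3),
    simple_register("P6", geography_id = "north", population_share = 0.4))
  expect_error(group_analysis_units(bad), "conflicting population_share")
  # generator bookkeeping: unit count per country equals geography count
  gen <- make_project_register(13)
  scr <- screen_projects(gen$register, gen$library)
  units2 <- group_analysis_units(scr$eligible)
  counts <- table(vapply(units2, `[[`, character(1), "country_id"))
  for (cid in names(gen$meta$geographies_per_country))
    expect_equal(unname(counts[[cid]]),
                 unname(gen$meta$geographies_per_country[[cid]]))
})

test_that("indicator values convert to coverage under the standard assumptions", {
  expect_equal(indicator_to_coverage(30000, "services_delivered", 50000), 0.6)
  expect_warning(
    clipped <- indicator_to_coverage(120000, "commodities", 100000),
    "clipping")
  expect_equal(clipped, 1)
  expect_equal(indicator_to_coverage(0.45, "coverage"), 0.45)
  expect_equal(indicator_to_coverage(40000, "message_exposure", 100000,
                                     behaviour_conversion = 0.5), 0.2)
  expect_true(is.na(indicator_to_coverage(1, "milestone")))
  expect_error(indicator_to_coverage(100, "services_delivered", NA),
               "target_population")
  expect_error(indicator_to_coverage(1.2, "coverage"), "\\[0,1\\]")
})

test_that("achieved values take precedence over forecasts", {
  expect_equal(resolve_value(0.5, 0.7), list(value = 0.5, provenance = "achieved"))
  expect_equal(resolve_value(NA, 0.7), list(value = 0.7, provenance = "forecast"))
  expect_equal(resolve_value(0.5, NA), list(value = 0.5, provenance = "achieved"))
  expect_error(resolve_value(NA, NA), "neither")
})

test_that("overlapping fragments merge by maximum, never by sum", {
  expect_equal(merge_coverage(0.4), 0.4)
  expect_message(m <- merge_coverage(c(0.4, 0.6)), "de-duplicating")
  expect_equal(m, 0.6)
  # idempotence: merging a value with itself is a no-op
  expect_equal(suppressMessages(merge_coverage(c(0.4, 0.4))), 0.4)
  expect_error(merge_coverage(NA_real_), "at least one")
})

test_that("the counterfactual scales the coverage increment by 1 - attribution", {
  prof <- tiny_profile()
  base <- flat_trajectory(prof, "neonatal_care")
  traj <- with_coverage(base, "neonatal_care", 0.7)
  # attribution 0: the counterfactual is the actual trajectory
  expect_equal(build_counterfactual(traj, base, 0)$cov, traj$cov)
  # attribution 1: the counterfactual collapses to baseline
  expect_equal(build_counterfactual(traj, base, 1)$cov, base$cov)
  # attribution 0.4, cov0 0.2, cov 0.7 -> 0.2 + 0.6 * 0.5 = 0.5
  cf <- build_counterfactual(traj, base, 0.4)
  expect_equal(unname(cf$cov["neonatal_care", "2013"]), 0.5)
  expect_error(build_counterfactual(traj, base, 1.2), "\\[0,1\\]")
})

test_that("achieved mode truncates the horizon; forecast mode extends it", {
  lib <- tiny_library()
  prof <- tiny_profile()
  reg <- simple_register(values = c(`2011` = 0.4, `2012` = 0.5, `2013` = 0.6,
                                    `2014` = 0.7, `2015` = 0.8),
                         provenance = c("achieved", "achieved", "achieved",
                                        "forecast", "forecast"))
  unit <- group_analysis_units(screen_projects(reg, lib)$eligible)[[1]]
  pair_a <- assemble_scenarios(unit, prof, lib, "achieved")
  pair_f <- assemble_scenarios(unit, prof, lib, "forecast")
  expect_equal(pair_a$meta$horizon, 2013)
  expect_equal(pair_f$meta$horizon, 2015)
  # achieved-mode result never covers years beyond the last achieved year
  res_a <- run_unit_analysis(pair_a, lib)
  expect_true(max(res_a$years) <= 2013)
  # an all-forecast unit has zero usable years in achieved mode
  reg_fc <- simple_register(provenance = "forecast")
  unit_fc <- group_analysis_units(screen_projects(reg_fc, lib)$eligible)[[1]]
  expect_error(assemble_scenarios(unit_fc, prof, lib, "achieved"),
               "zero usable years")
})

test_that("zero attribution yields an all-zero end-to-end result", {
  lib <- tiny_library()
  prof <- tiny_profile()
  reg <- simple_register(attribution = 0)
  res <- run_country_analysis(reg, prof, lib, "forecast")
  expect_true(all(vapply(res$series, function(s) all(s == 0), logical(1))))
  expect_true(all(res$per_intervention == 0))
})

test_that("lives saved grow monotonically with the attribution fraction", {
  lib <- tiny_library()
  prof <- tiny_profile()
  totals <- vapply(seq(0, 1, by = 0.25), function(a) {
    res <- run_country_analysis(simple_register(attribution = a), prof, lib,
                                "forecast")
    res$totals[["newborn_primary"]]
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_equal(totals[[1]], 0)
})

test_that("de-duplication bookkeeping matches the generator's injected overlaps", {
  gen <- make_project_register(17, params = list(n_duplicate_pairs = 3))
  units <- unlist(lapply(names(gen$profiles), function(cid) {
    r <- run_country_analysis(gen$register[gen$register$country_id == cid, ],
                              gen$profiles[[cid]], gen$library, "forecast")
    vapply(attr(r, "units"), `[[`, integer(1), "n_duplicate_fragments")
  }))
  expect_equal(sum(units), gen$meta$n_duplicate_fragments)
})

test_that("aggregation is additive: global equals sum of countries and units", {
  gen <- make_project_register(19)
  country_results <- lapply(names(gen$profiles), function(cid)
    run_country_analysis(gen$register[gen$register$country_id == cid, ],
                         gen$profiles[[cid]], gen$library, "forecast"))
  g <- aggregate_global(country_results)
  resum <- combine_results(country_results, country_id = "GLOBAL")
  expect_equal(g$series, resum$series)
  for (nm in names(g$totals))
    expect_equal(g$totals[[nm]],
                 sum(vapply(country_results, function(r) r$totals[[nm]],
                            numeric(1))), tolerance = 1e-9)
  # single-country identity
  g1 <- aggregate_global(country_results[1])
  expect_equal(g1$series, country_results[[1]]$series)
  expect_equal(g1$totals, country_results[[1]]$totals)
})
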