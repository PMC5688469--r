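test_that("Bongaarts index matches direct evaluation and rejects impossible inputs", {
  expect_equal(bongaarts_index(0, 0.9), 1.0)
  expect_equal(bongaarts_index(0.1, 0.9), 0.9028)
  expect_equal(bongaarts_index(0.3, 0.9), 0.7084)
  expect_error(bongaarts_index(1, 1), "non-positive fertility index")
  expect_error(bongaarts_index(-0.1, 0.9), "\\[0,1\\]")
})

test_that("births projection follows the TFR/Bongaarts formula", {
  prof <- tiny_profile()
  # unchanged prevalence: births constant at W * TFR/35 = 100,000
  cp <- stats::setNames(rep(0.1, 6), 2010:2015)
  b <- project_births(prof, cp)
  expect_equal(unname(b), rep(100000, 6))
  # hand evaluation: cp 0.1 -> 0.3 in 2013
  b13 <- project_births(prof, c(`2013` = 0.3))
  expect_equal(unname(b13), 100000 * 0.7084 / 0.9028, tolerance = 1e-12)
  # population share scales proportionally
  b_half <- project_births(prof, cp, population_share = 0.5)
  expect_equal(unname(b_half), unname(b) / 2)
  expect_error(project_births(prof, c(`2011` = 0.1), years = 2012),
               "2012")
})

test_that("residual factor is a product over matching effects, order-invariant", {
  lib <- tiny_library()
  # no matching interventions -> empty product
  expect_equal(residual_factor(lib, c(safe_birth = 0.9), "neonatal",
                               "prematurity"), 1.0)
  # single effect: 1 - 0.5 * 1 * 0.6
  expect_equal(residual_factor(lib, c(neonatal_care = 0.6), "neonatal",
                               "prematurity"), 0.7)
  # two effects multiply commutatively regardless of declaration order
  eff1 <- data.frame(target_group = "neonatal", cause = "prematurity",
                     effectiveness = 0.5, affected_fraction = 1)
  eff2 <- data.frame(target_group = "neonatal", cause = "prematurity",
                     effectiveness = 0.2, affected_fraction = 1)
  a <- intervention_spec("a", period = "pregnancy", category = "preventive",
                         effects = eff1)
  b <- intervention_spec("b", period = "postnatal", category = "curative",
                         effects = eff2)
  cov <- c(a = 0.6, b = 0.5)
  rf12 <- residual_factor(intervention_library(a, b), cov, "neonatal",
                          "prematurity")
  rf21 <- residual_factor(intervention_library(b, a), cov, "neonatal",
                          "prematurity")
  expect_equal(rf12, 0.7 * 0.9)
  expect_identical(rf12, rf21)
  expect_error(residual_factor(lib, c(nonexistent = 0.5), "neonatal",
                               "prematurity"), "unknown intervention")
})

test_that("projection normalizes to baseline and matches hand arithmetic", {
  prof <- tiny_profile()
  lib <- tiny_library()
  # flat trajectory: deaths reproduce the baseline rates every year
  scn <- scenario(prof, flat_trajectory(prof, names(lib)), "with_funder")
  res <- run_projection(scn, lib)
  expect_equal(unname(colSums(res$neonatal_deaths)), rep(3000, 6))
  expect_equal(unname(colSums(res$maternal_deaths)), rep(300, 6))
  # coverage 0.2 -> 0.6 rescales neonatal deaths by 0.7/0.9
  scn2 <- scenario(prof, with_coverage(flat_trajectory(prof, names(lib)),
                                       "neonatal_care", 0.6), "with_funder")
  res2 <- run_projection(scn2, lib)
  expect_equal(unname(colSums(res2$neonatal_deaths)[-1]),
               rep(3000 * 0.7 / 0.9, 5))
  # baseline saturation: an effectiveness-1 effect at full baseline coverage
  sat <- intervention_library(
    intervention_spec("sat", period = "postnatal", category = "curative",
                      effects = data.frame(target_group = "neonatal",
                                           cause = "prematurity",
                                           effectiveness = 1,
                                           affected_fraction = 1)))
  prof_sat <- tiny_profile(baseline_coverage = c(sat = 1))
  scn_sat <- scenario(prof_sat, flat_trajectory(prof_sat, "sat"),
                      "with_funder")
  expect_error(run_projection(scn_sat, sat), "saturates")
})

test_that("lives saved is the paired difference: identity, hand value, antisymmetry", {
  prof <- tiny_profile()
  lib <- tiny_library()
  base <- flat_trajectory(prof, names(lib))
  with_scn <- scenario(prof, with_coverage(base, "neonatal_care", 0.6),
                       "with_funder")
  without_scn <- scenario(prof, base, "without_funder")
  res_w <- run_projection(with_scn, lib)
  res_wo <- run_projection(without_scn, lib)
  # identical projections save nobody
  ls0 <- lives_saved(res_wo, res_wo)
  expect_true(all(ls0$newborn == 0) && all(ls0$maternal == 0))
  # 3000 - 2333.3 = 666.7 per year, 3333.3 over 2011-2015
  ls <- lives_saved(res_w, res_wo)
  expect_equal(unname(ls$newborn), rep(3000 * (1 - 0.7 / 0.9), 5))
  expect_equal(sum(ls$newborn), 5 * 3000 * (1 - 0.7 / 0.9))
  # swapping the arguments negates every value (reported, not clipped)
  expect_warning(ls_neg <- lives_saved(res_wo, res_w), "negative")
  expect_equal(ls_neg$newborn, -ls$newborn)
  # year mismatch is a hard error
  res_short <- res_wo
  res_short$years <- res_short$years[-1]
  expect_error(lives_saved(res_w, res_short), "same years")
})

test_that("family-planning decomposition is additive and degenerates correctly", {
  prof <- tiny_profile()
  lib <- tiny_library()
  base <- flat_trajectory(prof, names(lib))

  # health-only portfolio: fp component identically zero
  w <- with_coverage(base, "neonatal_care", 0.6)
  s <- function(traj, lab) scenario(prof, traj, lab)
  d <- decompose_fp_health(run_projection(s(w, "with_funder"), lib),
                           run_projection(s(base, "without_funder"), lib),
                           run_projection(s(w, "with_funder"), lib),
                           run_projection(s(base, "without_funder"), lib))
  expect_true(all(d$maternal_fp == 0))
  expect_equal(d$maternal_total, d$maternal_health)

  # fp-only portfolio: no direct-health component at all
  fp_traj <- with_coverage(base, "fp_modern_methods", 0.3)
  fp_traj <- coverage_trajectory(fp_traj$cov,
    stats::setNames(c(prof$cp0, rep(0.3, 5)), 2010:2015))
  health_wo <- coverage_trajectory(base$cov, fp_traj$cp)
  d2 <- decompose_fp_health(
    run_projection(s(fp_traj, "with_funder"), lib),
    run_projection(s(base, "without_funder"), lib),
    run_projection(s(fp_traj, "with_funder"), lib),
    run_projection(s(health_wo, "without_funder"), lib))
  expect_true(all(d2$maternal_health == 0))
  expect_true(all(d2$newborn_primary == 0))
  expect_true(all(d2$maternal_fp > 0))  # fewer births, fewer maternal deaths

  # mixed portfolio: additivity holds exactly each year
  mix_w <- with_coverage(fp_traj, "neonatal_care", 0.6)
  mix_hwo <- coverage_trajectory(base$cov, fp_traj$cp)
  d3 <- decompose_fp_health(
    run_projection(s(mix_w, "with_funder"), lib),
    run_projection(s(base, "without_funder"), lib),
    run_projection(s(mix_w, "with_funder"), lib),
    run_projection(s(mix_hwo, "without_funder"), lib))
  expect_equal(d3$maternal_fp + d3$maternal_health, d3$maternal_total)
  # profiles must match across the pairs
  other <- run_projection(s(base, "without_funder"), lib)
  other$country_id <- "OTHER"
  expect_error(decompose_fp_health(other,
    run_projection(s(base, "without_funder"), lib),
    run_projection(s(base, "with_funder"), lib),
    run_projection(s(base, "without_funder"), lib)), "different profiles")
})

test_that("per-intervention attribution conserves the total and respects symmetry", {
  prof <- country_profile(
    "SYM", tfr0 = 5, women_reproductive_age = 700000, nmr0 = 30, mmr0 = 300,
    neonatal_cause_fractions = c(prematurity = 1),
    maternal_cause_fractions = c(haemorrhage = 1),
    baseline_coverage = c(a = 0.2, b = 0.2), cp0 = 0.1)
  eff <- data.frame(target_group = "neonatal", cause = "prematurity",
                    effectiveness = 0.4, affected_fraction = 1)
  lib <- intervention_library(
    intervention_spec("a", period = "pregnancy", category = "preventive",
                      effects = eff),
    intervention_spec("b", period = "postnatal", category = "curative",
                      effects = eff))
  base <- flat_trajectory(prof, names(lib))
  up <- with_coverage(with_coverage(base, "a", 0.6), "b", 0.6)
  pair <- list(with = scenario(prof, up, "with_funder"),
               without = scenario(prof, base, "without_funder"))
  shares <- per_intervention_attribution(pair, lib)
  total <- sum(lives_saved(run_projection(pair$with, lib),
                           run_projection(pair$without, lib))$newborn)
  # identical interventions with identical coverage changes: equal shares
  expect_equal(shares[["a"]], shares[["b"]])
  expect_equal(sum(shares), total, tolerance = 1e-9)

  # single intervention receives 100%
  up_a <- with_coverage(base, "a", 0.6)
  pair_a <- list(with = scenario(prof, up_a, "with_funder"),
                 without = scenario(prof, base, "without_funder"))
  shares_a <- per_intervention_attribution(pair_a, lib)
  total_a <- sum(lives_saved(run_projection(pair_a$with, lib),
                             run_projection(pair_a$without, lib))$newborn)
  expect_equal(shares_a[["a"]], total_a, tolerance = 1e-9)
  expect_equal(shares_a[["b"]], 0)
})

test_that("log-residual shares agree with a leave-one-out oracle on the total", {
  prof <- country_profile(
    "LOO", tfr0 = 5, women_reproductive_age = 700000, nmr0 = 30, mmr0 = 300,
    neonatal_cause_fractions = c(prematurity = 1),
    maternal_cause_fractions = c(haemorrhage = 1),
    baseline_coverage = c(a = 0.1, b = 0.3), cp0 = 0.1)
  lib <- intervention_library(
    intervention_spec("a", period = "pregnancy", category = "preventive",
                      effects = data.frame(target_group = "neonatal",
                                           cause = "prematurity",
                                           effectiveness = 0.6,
                                           affected_fraction = 0.8)),
    intervention_spec("b", period = "postnatal", category = "curative",
                      effects = data.frame(target_group = "neonatal",
                                           cause = "prematurity",
                                           effectiveness = 0.3,
                                           affected_fraction = 1)))
  base <- flat_trajectory(prof, names(lib))
  up <- with_coverage(with_coverage(base, "a", 0.5), "b", 0.8)
  pair <- list(with = scenario(prof, up, "with_funder"),
               without = scenario(prof, base, "without_funder"))
  shares <- per_intervention_attribution(pair, lib)
  total <- sum(lives_saved(run_projection(pair$with, lib),
                           run_projection(pair$without, lib))$newborn)
  expect_equal(sum(shares), total, tolerance = 1e-9)

  # brute-force leave-one-out: drop one intervention's change at a time
  loo <- vapply(c("a", "b"), function(id) {
    held <- up
    held$cov[id, ] <- base$cov[id, ]
    held <- coverage_trajectory(held$cov, held$cp)
    total - sum(lives_saved(
      run_projection(scenario(prof, held, "with_funder"), lib),
      run_projection(pair$without, lib))$newborn)
  }, numeric(1))
  # raw leave-one-out marginals are a different decomposition ...
  expect_false(isTRUE(all.equal(unname(loo), unname(shares))))
  # ... but normalized to the total they allocate the same quantity
  expect_equal(sum(loo / sum(loo) * total), total, tolerance = 1e-9)
})

test_that("increasing with-funder coverage never loses lives (monotonicity)", {
  prof <- tiny_profile()
  lib <- tiny_library()
  base <- flat_trajectory(prof, names(lib))
  without_res <- run_projection(scenario(prof, base, "without_funder"), lib)
  totals <- vapply(seq(0.2, 1, by = 0.1), function(cv) {
    w <- with_coverage(base, "neonatal_care", cv)
    sum(lives_saved(run_projection(scenario(prof, w, "with_funder"), lib),
                    without_res)$newborn)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})
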