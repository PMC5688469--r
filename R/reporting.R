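#' Integer percentage, rounded half away from zero
#'
#' The convention used throughout the round summaries: `100 * n / d`
#' rounded to the nearest integer, with halves rounded away from zero
#' (unlike [round()], which rounds halves to even).
#'
#' @param n_analysed,n_reported Non-negative counts with
#'   `n_analysed <= n_reported` and `n_reported > 0`.
#' @return Integer percent in `[0, 100]`.
#' @examples
#' percent_analysed(151, 182) # 83
#' @export
percent_analysed <- function(n_analysed, n_reported) {
  if (n_reported <= 0) stop("n_reported must be positive")
  if (n_analysed < 0 || n_analysed > n_reported)
    stop("need 0 <= n_analysed <= n_reported")
  p <- 100 * n_analysed / n_reported
  as.integer(floor(p + 0.5))
}

#' Summarize data completeness of a register
#'
#' A country counts as having achieved data if any of its entry-years
#' carries a non-missing value with provenance `"achieved"`.
#'
#' @param register A project-register tibble.
#' @return A list with `countries_total`, `countries_with_achieved`, and
#'   `percent_with_achieved`.
#' @export
completeness_summary <- function(register) {
  by_country <- dplyr::summarise(
    dplyr::group_by(register, .data$country_id),
    has_achieved = any(.data$provenance == "achieved" & !is.na(.data$value)))
  n_total <- nrow(by_country)
  n_ach <- sum(by_country$has_achieved)
  list(countries_total = n_total,
       countries_with_achieved = n_ach,
       percent_with_achieved = if (n_total > 0)
         percent_analysed(n_ach, n_total) else NA_integer_)
}

#' Summarize an analysis round
#'
#' Counts reporting countries, analysis units, analysed versus reported
#' projects and the inclusion percentage, plus the achieved-data
#' completeness — the per-round bookkeeping published alongside the
#' lives-saved estimates.
#'
#' @param register The round's full project register.
#' @param screening Output of [screen_projects()] on that register.
#' @param units List of analysis units (e.g. from [group_analysis_units()]
#'   or the `units` attribute of the country results), or an integer count.
#' @param round_label Free-text label for the round.
#' @return A one-row tibble of class `round_summary`.
#' @export
summarize_round <- function(register, screening, units,
                            round_label = "") {
  n_reported <- length(unique(register$project_id))
  n_analysed <- length(unique(screening$eligible$project_id))
  comp <- completeness_summary(register)
  out <- tibble::tibble(
    round_label = round_label,
    countries_reporting = length(unique(register$country_id)),
    analyses = if (is.numeric(units)) as.integer(units) else length(units),
    projects_analysed = n_analysed,
    projects_reported = n_reported,
    percent_analysed = percent_analysed(n_analysed, n_reported),
    countries_with_achieved = comp$countries_with_achieved,
    percent_with_achieved = comp$percent_with_achieved
  )
  class(out) <- c("round_summary", class(out))
  out
}

#' Sensitivity of the lives-saved totals to the mortality source
#'
#' Reruns the entire pipeline once per mortality-estimate source,
#' substituting only the baseline NMR/MMR into each country profile, and
#' reports the resulting range of the maternal and newborn totals. The
#' default source is `"IGME"` when available, otherwise the first label.
#' Because the projections are linear in the baseline rates for a fixed
#' set of coverage trajectories, newborn totals scale exactly with the
#' substituted NMR and maternal totals with the substituted MMR.
#'
#' @param register Multi-country project register.
#' @param profiles Named list of [country_profile()]s keyed by country id.
#' @param library An [intervention_library()].
#' @param sources Mortality-source tibble (see
#'   [read_mortality_sources()]); every listed country must appear under
#'   every source label used.
#' @param mode `"achieved"` or `"forecast"`.
#' @param behaviour_conversion Message-exposure conversion factor.
#' @return A list of class `sensitivity_range`: `table` (tibble
#'   `source_label`, `maternal_total`, `newborn_primary`), `default_source`,
#'   and per-outcome `min`, `max`, `default` values.
#' @export
run_mortality_sensitivity <- function(register, profiles, library, sources,
                                      mode = c("achieved", "forecast"),
                                      behaviour_conversion = 1) {
  mode <- match.arg(mode)
  labels <- unique(sources$source_label)
  if (length(labels) == 0) stop("no mortality sources supplied")
  default <- if ("IGME" %in% labels) "IGME" else labels[[1]]
  rows <- lapply(labels, function(lab) {
    country_results <- lapply(names(profiles), function(cid) {
      prof <- apply_mortality_source(profiles[[cid]], sources, lab)
      run_country_analysis(register[register$country_id == cid, ],
                           prof, library, mode, behaviour_conversion)
    })
    g <- aggregate_global(country_results)
    tibble::tibble(source_label = lab,
                   maternal_total = g$totals[["maternal_total"]],
                   newborn_primary = g$totals[["newborn_primary"]])
  })
  table <- dplyr::bind_rows(rows)
  rng <- function(col) {
    list(min = min(table[[col]]), max = max(table[[col]]),
         default = table[[col]][table$source_label == default])
  }
  structure(list(table = table, default_source = default,
                 maternal_total = rng("maternal_total"),
                 newborn_primary = rng("newborn_primary")),
            class = "sensitivity_range")
}

#' @export
print.sensitivity_range <- function(x, ...) {
  cat("<sensitivity_range> default source: ", x$default_source, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Write analysis results to CSV files
#'
#' Emits `annual_lives_saved.csv` (country, year, series, value),
#' `per_intervention.csv` (country, intervention_id, total),
#' `round_summary.csv`, and, when a sensitivity analysis is supplied,
#' `sensitivity.csv` (country_id, source_label, outcome, total). Rows are
#' sorted deterministically (country, year, series), so repeated runs on
#' identical inputs produce byte-identical files, and values survive a
#' read-back round trip to within 1e-9.
#'
#' @param global A [lives_saved_result()] from [aggregate_global()] (its
#'   `by_country` attribute supplies the per-country rows).
#' @param out_dir Output directory, created if needed.
#' @param round_summary Optional [summarize_round()] tibble.
#' @param sensitivity Optional `sensitivity_range`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(global, out_dir, round_summary = NULL,
                          sensitivity = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  results <- c(attr(global, "by_country"), list(global))

  annual <- dplyr::bind_rows(lapply(results, tidy_result))
  annual <- dplyr::arrange(annual, .data$country_id, .data$year, .data$series)
  files <- c(annual = file.path(out_dir, "annual_lives_saved.csv"))
  utils::write.csv(annual, files[["annual"]], row.names = FALSE)

  pi_rows <- dplyr::bind_rows(lapply(results, function(r) {
    if (length(r$per_intervention) == 0) return(NULL)
    tibble::tibble(country_id = r$country_id,
                   intervention_id = names(r$per_intervention),
                   total = unname(r$per_intervention))
  }))
  if (is.null(pi_rows) || nrow(pi_rows) == 0)
    pi_rows <- tibble::tibble(country_id = character(),
                              intervention_id = character(),
                              total = numeric())
  pi_rows <- dplyr::arrange(pi_rows, .data$country_id, .data$intervention_id)
  files <- c(files, per_intervention = file.path(out_dir, "per_intervention.csv"))
  utils::write.csv(pi_rows, files[["per_intervention"]], row.names = FALSE)

  if (!is.null(round_summary)) {
    files <- c(files, round_summary = file.path(out_dir, "round_summary.csv"))
    utils::write.csv(as.data.frame(round_summary), files[["round_summary"]],
                     row.names = FALSE)
  }
  if (!is.null(sensitivity)) {
    sens <- tidyr_pivot_sensitivity(sensitivity)
    files <- c(files, sensitivity = file.path(out_dir, "sensitivity.csv"))
    utils::write.csv(sens, files[["sensitivity"]], row.names = FALSE)
  }
  invisible(files)
}

# long form of the sensitivity table: country_id (GLOBAL), source, outcome, total
tidyr_pivot_sensitivity <- function(sensitivity) {
  t <- sensitivity$table
  out <- dplyr::bind_rows(
    tibble::tibble(country_id = "GLOBAL", source_label = t$source_label,
                   outcome = "maternal_total", total = t$maternal_total),
    tibble::tibble(country_id = "GLOBAL", source_label = t$source_label,
                   outcome = "newborn_primary", total = t$newborn_primary))
  dplyr::arrange(out, .data$country_id, .data$source_label, .data$outcome)
}
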