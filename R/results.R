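#' Lives-saved result container
#'
#' Holds the annual lives-saved series for one analysis unit, one country
#' or the global aggregate: total, family-planning-mediated and
#' direct-health maternal lives saved, the primary (direct-health) newborn
#' series, the auxiliary fertility-mediated newborn series (excluded from
#' headline totals), per-intervention attribution, and totals summed over
#' the post-baseline years.
#'
#' @param series List of annual named numeric vectors `maternal_total`,
#'   `maternal_fp`, `maternal_health`, `newborn_primary`,
#'   `newborn_fertility`, all keyed by the same years.
#' @param per_intervention Named numeric vector of total lives saved per
#'   intervention id.
#' @param country_id Country label, or `"GLOBAL"` for aggregates.
#' @param n_units Number of analysis units summed into this result.
#' @return An object of class `lives_saved_result`.
#' @export
lives_saved_result <- function(series, per_intervention = numeric(),
                               country_id = NA_character_, n_units = 1L) {
  needed <- c("maternal_total", "maternal_fp", "maternal_health",
              "newborn_primary", "newborn_fertility")
  if (!all(needed %in% names(series)))
    stop("series must contain: ", paste(needed, collapse = ", "))
  yrs <- names(series$maternal_total)
  for (nm in needed) {
    if (!identical(names(series[[nm]]), yrs))
      stop("all series must share the same years")
  }
  gap <- series$maternal_fp + series$maternal_health - series$maternal_total
  if (length(gap) && max(abs(gap)) > 1e-6)
    stop("maternal_fp + maternal_health must equal maternal_total")
  structure(
    list(series = series[needed],
         per_intervention = per_intervention,
         totals = vapply(series[needed], sum, numeric(1)),
         years = as.integer(yrs),
         country_id = country_id,
         n_units = as.integer(n_units)),
    class = "lives_saved_result"
  )
}

#' @export
print.lives_saved_result <- function(x, ...) {
  cat("<lives_saved_result> ",
      if (is.na(x$country_id)) "" else paste0(x$country_id, ", "),
      length(x$years), " year(s), ", x$n_units, " analysis unit(s)\n",
      sep = "")
  t <- x$totals
  cat(sprintf("  maternal: %.1f total (%.1f family planning + %.1f direct health)\n",
              t[["maternal_total"]], t[["maternal_fp"]], t[["maternal_health"]]))
  cat(sprintf("  newborn:  %.1f primary (+ %.1f fertility-mediated, auxiliary)\n",
              t[["newborn_primary"]], t[["newborn_fertility"]]))
  invisible(x)
}

#' Sum lives-saved results elementwise
#'
#' Aligns annual series on the union of years (absent years count as
#' zero), sums per-intervention attributions by id, and recomputes totals.
#' Used to aggregate analysis units into a national result and national
#' results into the global estimate.
#'
#' @param results List of `lives_saved_result` objects.
#' @param country_id Label for the combined result.
#' @return A `lives_saved_result`.
#' @export
combine_results <- function(results, country_id = NA_character_) {
  stopifnot(length(results) >= 1)
  yrs <- sort(unique(unlist(lapply(results, `[[`, "years"))))
  key <- as.character(yrs)
  series_names <- names(results[[1]]$series)
  series <- lapply(series_names, function(nm) {
    acc <- stats::setNames(rep(0, length(key)), key)
    for (r in results) acc[names(r$series[[nm]])] <-
        acc[names(r$series[[nm]])] + r$series[[nm]]
    acc
  })
  names(series) <- series_names
  pi_ids <- sort(unique(unlist(lapply(results, function(r) names(r$per_intervention)))))
  pi <- stats::setNames(rep(0, length(pi_ids)), pi_ids)
  for (r in results) pi[names(r$per_intervention)] <-
      pi[names(r$per_intervention)] + r$per_intervention
  lives_saved_result(series, pi, country_id = country_id,
                     n_units = sum(vapply(results, `[[`, integer(1), "n_units")))
}

#' Tidy a lives-saved result into a long tibble
#'
#' @param x A `lives_saved_result`.
#' @return A tibble with columns `country_id`, `year`, `series`, `value`.
#' @export
tidy_result <- function(x) {
  stopifnot(inherits(x, "lives_saved_result"))
  rows <- lapply(names(x$series), function(nm) {
    tibble::tibble(country_id = x$country_id,
                   year = x$years,
                   series = nm,
                   value = unname(x$series[[nm]]))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$year, .data$series)
}
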