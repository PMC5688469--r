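# File formats: country profiles and intervention libraries travel as
# YAML or JSON; registers and mortality-source tables as UTF-8 CSV with a
# header. The synthetic-data generators write the same formats, so
# fixtures round-trip through these parsers.

read_structured <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("expected a .yaml/.yml or .json file: ", path)
  }
}

#' Read a country profile from YAML or JSON
#'
#' The schema mirrors the [country_profile()] arguments; cause labels are
#' free-form but must be consistent with the intervention library in use.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [country_profile()].
#' @export
read_country_profile <- function(path) {
  x <- read_structured(path)
  country_profile(
    country_id = x$country_id,
    tfr0 = x$tfr0,
    women_reproductive_age = unlist(x$women_reproductive_age),
    nmr0 = x$nmr0,
    mmr0 = x$mmr0,
    neonatal_cause_fractions = unlist(x$neonatal_cause_fractions),
    maternal_cause_fractions = unlist(x$maternal_cause_fractions),
    baseline_coverage = if (length(x$baseline_coverage))
      unlist(x$baseline_coverage) else numeric(),
    cp0 = x$cp0,
    contraceptive_effectiveness = x$contraceptive_effectiveness %||% 0.9,
    baseline_year = x$baseline_year %||% 2010L,
    horizon_year = x$horizon_year %||% 2015L,
    mortality_source = x$mortality_source %||% "IGME"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a country profile to YAML
#'
#' @param profile A [country_profile()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_country_profile <- function(profile, path) {
  x <- unclass(profile)
  x$neonatal_cause_fractions <- as.list(x$neonatal_cause_fractions)
  x$maternal_cause_fractions <- as.list(x$maternal_cause_fractions)
  x$baseline_coverage <- as.list(x$baseline_coverage)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read an intervention library from YAML or JSON
#'
#' Expects a list of entries with fields `intervention_id`, `name`,
#' `period`, `category`, `is_family_planning`, and `effects` (a list of
#' records with `target_group`, `cause`, `effectiveness`,
#' `affected_fraction`; the affected fraction defaults to 1 when omitted).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [intervention_library()].
#' @export
read_intervention_library <- function(path) {
  entries <- read_structured(path)
  if (!is.null(entries$interventions)) entries <- entries$interventions
  specs <- lapply(entries, function(e) {
    eff <- e$effects
    eff_df <- if (length(eff)) {
      do.call(rbind, lapply(eff, function(f) {
        data.frame(target_group = f$target_group, cause = f$cause,
                   effectiveness = f$effectiveness,
                   affected_fraction = f$affected_fraction %||% 1,
                   stringsAsFactors = FALSE)
      }))
    } else NULL
    intervention_spec(e$intervention_id, e$name %||% e$intervention_id,
                      e$period, e$category, eff_df,
                      is_family_planning = isTRUE(e$is_family_planning))
  })
  intervention_library(specs)
}

#' Write an intervention library to YAML
#'
#' @param library An [intervention_library()].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_intervention_library <- function(library, path) {
  entries <- lapply(unname(library), function(s) {
    list(intervention_id = s$intervention_id, name = s$name,
         period = s$period, category = s$category,
         is_family_planning = s$is_family_planning,
         effects = lapply(seq_len(nrow(s$effects)), function(i) {
           as.list(s$effects[i, c("target_group", "cause", "effectiveness",
                                  "affected_fraction")])
         }))
  })
  yaml::write_yaml(list(interventions = entries), path, precision = 15)
  invisible(path)
}

register_columns <- c("project_id", "country_id", "management",
                      "start_year", "end_year", "total_funding",
                      "attribution", "geography_id", "population_share",
                      "intervention_id", "indicator_type", "year", "value",
                      "provenance", "target_population")

#' Read a project register CSV
#'
#' One row per (project, intervention, year): the country-office template
#' flattened. Required columns: `r paste(register_columns, collapse = ", ")`.
#'
#' @param path Path to a UTF-8 CSV with a header.
#' @return A validated tibble.
#' @export
read_project_register <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_register(tibble::as_tibble(df))
}

#' @rdname read_project_register
#' @param register A register tibble to validate.
#' @export
validate_register <- function(register) {
  missing_cols <- setdiff(register_columns, names(register))
  if (length(missing_cols))
    stop("register is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(register$management %in% c("bilateral", "central_multicountry",
                                      "multilateral")))
    stop("management must be bilateral, central_multicountry or multilateral")
  if (!all(register$provenance %in% c("achieved", "forecast")))
    stop("provenance must be 'achieved' or 'forecast'")
  if (any(register$attribution < 0 | register$attribution > 1, na.rm = TRUE))
    stop("attribution must lie in [0,1]")
  if (any(register$population_share <= 0 | register$population_share > 1,
          na.rm = TRUE))
    stop("population_share must lie in (0,1]")
  bad <- with(register, indicator_type == "coverage" & !is.na(value) &
                (value < 0 | value > 1))
  if (any(bad))
    stop("coverage-type values must lie in [0,1]")
  if (any(register$value < 0, na.rm = TRUE))
    stop("indicator values must be non-negative")
  if (any(register$start_year > register$end_year))
    stop("start_year must not exceed end_year")
  register
}

#' Write a project register CSV
#'
#' @param register A register tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_project_register <- function(register, path) {
  utils::write.csv(register[register_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a mortality-source table
#'
#' CSV columns `country_id`, `source_label`, `nmr`, `mmr` — one row per
#' country and mortality-estimate source (e.g. IGME, IHME, DHS).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_mortality_sources <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("country_id", "source_label", "nmr", "mmr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("mortality-source table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(df$nmr < 0 | df$mmr < 0))
    stop("mortality rates must be non-negative")
  df
}

#' Substitute a mortality source into a country profile
#'
#' Replaces only the baseline NMR and MMR (and the source label); all
#' other profile fields are untouched, so sensitivity reruns differ from
#' the default analysis only through the baseline mortality level.
#'
#' @param profile A [country_profile()].
#' @param sources Tibble from [read_mortality_sources()].
#' @param source_label Which source to apply.
#' @return The modified [country_profile()].
#' @export
apply_mortality_source <- function(profile, sources, source_label) {
  row <- sources[sources$country_id == profile$country_id &
                   sources$source_label == source_label, ]
  if (nrow(row) == 0)
    stop("no mortality estimates for ", profile$country_id,
         " from source ", source_label)
  profile$nmr0 <- row$nmr[[1]]
  profile$mmr0 <- row$mmr[[1]]
  profile$mortality_source <- source_label
  validate_country_profile(profile)
}
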