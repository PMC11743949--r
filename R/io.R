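#' Write an athlete cohort to CSV (plus JSON sidecars)
#'
#' The CSV has the documented schema `athlete_id, position, regime,
#' f0..f{D-1}, inj_<site>...`. The latent training groups and, when present,
#' the generating configuration are written as JSON next to the CSV
#' (`<path>.groups.json`, `<path>.config.json`) so the round trip is
#' lossless.
#'
#' @param cohort an `athlete_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "athlete_cohort"))
  atomic_write(function(tmp) {
    readr::write_csv(tibble::as_tibble(cohort), tmp)
  }, path)
  groups <- cohort_groups(cohort)
  if (!is.null(groups)) {
    atomic_write(function(tmp) {
      jsonlite::write_json(lapply(groups, as.integer), tmp, digits = NA)
    }, paste0(path, ".groups.json"))
  }
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    atomic_write(function(tmp) {
      jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
    }, paste0(path, ".config.json"))
  }
  invisible(path)
}

#' Read an athlete cohort from CSV
#'
#' Validates the schema: `athlete_id`, `position` and `regime` columns must
#' be present, `regime` must contain only `traditional` / `maft`, and every
#' `inj_*` column must be strictly binary; violations raise a schema error
#' naming the offending column.
#'
#' @param path CSV file path written by [write_cohort()].
#' @param groups_path optional path to the groups JSON; defaults to
#'   `<path>.groups.json` when that file exists.
#' @return an `athlete_cohort`.
#' @export
read_cohort <- function(path, groups_path = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("athlete_id", "position", "regime")) {
    if (!col %in% names(df)) {
      abort(sprintf("cohort file is missing required column '%s'.", col),
            class = "wpinjury_schema_error")
    }
  }
  if (!all(df$regime %in% c("traditional", "maft"))) {
    abort("column 'regime' must contain only 'traditional' or 'maft'.",
          class = "wpinjury_schema_error")
  }
  feat <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(feat) == 0L) {
    abort("cohort file has no feature columns 'f0..'.",
          class = "wpinjury_schema_error")
  }
  for (col in grep("^inj_", names(df), value = TRUE)) {
    if (!all(df[[col]] %in% c(0, 1))) {
      abort(sprintf("label column '%s' must be binary 0/1.", col),
            class = "wpinjury_schema_error")
    }
  }
  if (is.null(groups_path) && file.exists(paste0(path, ".groups.json"))) {
    groups_path <- paste0(path, ".groups.json")
  }
  groups <- if (!is.null(groups_path)) {
    lapply(jsonlite::read_json(groups_path, simplifyVector = FALSE),
           function(g) as.integer(unlist(g)))
  }
  new_athlete_cohort(df, groups = groups)
}

#' Write a metric table to TSV
#'
#' Keeps both the `mean±sd` summary strings and the separate numeric
#' columns.
#'
#' @param tab a `metric_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(tab, path) {
  atomic_write(function(tmp) {
    readr::write_tsv(tibble::as_tibble(tab), tmp)
  }, path)
}
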