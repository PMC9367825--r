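#' Read and validate a CSV table against a schema
#'
#' A schema is a named character vector mapping required column names to one
#' of `"character"`, `"integer"`, `"numeric"`, `"date"`, `"money"`,
#' `"logical"`. Dates must be ISO 8601 (YYYY-MM-DD); money columns are
#' parsed to numeric dollars exact to the cent. Validation failures name the
#' offending column and row.
#'
#' @param path CSV file path
#' @param schema named character vector of column types
#' @return a validated tibble (extra columns are kept as read)
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols))
    stop_data("%s: missing column(s): %s", basename(path), paste(missing_cols, collapse = ", "))
  for (col in names(schema)) {
    x <- raw[[col]]
    parsed <- switch(schema[[col]],
      character = x,
      logical = as.logical(x),
      integer = suppressWarnings(as.integer(x)),
      numeric = suppressWarnings(as.numeric(x)),
      money = round_cents(suppressWarnings(as.numeric(x))),
      date = as.Date(x, format = "%Y-%m-%d"),
      stop_data("unknown schema type '%s'", schema[[col]])
    )
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad))
      stop_data("%s: column '%s', row %d: cannot parse '%s' as %s",
                basename(path), col, bad[1], x[bad[1]], schema[[col]])
    raw[[col]] <- parsed
  }
  raw
}

lab_tests_schema <- c(participant_id = "character", test_date = "date", viral_load = "integer")

#' Read a viral-load test table
#' @param path CSV with participant_id, test_date (ISO 8601), viral_load
#' @return validated tibble
#' @export
read_lab_tests <- function(path) {
  x <- read_table(path, lab_tests_schema)
  bad <- which(is.na(x$viral_load) | x$viral_load < 0)
  if (length(bad))
    stop_data("%s: column 'viral_load', row %d: must be a non-negative count",
              basename(path), bad[1])
  x
}

#' Read a participants table
#' @param path CSV with id, enrollment_date, diagnosis_date, age_years plus
#'   covariate and survey columns
#' @return validated tibble
#' @export
read_participants <- function(path) {
  x <- read_table(path, c(id = "character", enrollment_date = "date",
                          diagnosis_date = "date", age_years = "numeric"))
  for (col in intersect(c("resident", "plans_to_move", "english_ok", "confirmed_hiv",
                          "in_other_study", "institutionalized", "unstable_housing",
                          "unemployed_3mo", "incarceration_history", "behavioral_health_12mo"),
                        names(x)))
    x[[col]] <- as.logical(x[[col]])
  for (col in intersect(c("missed_visits_6mo", "auditc_score", paste0("accept_", 1:4),
                          paste0("phq9_", 1:9), paste0("stigma_", 1:4)), names(x)))
    x[[col]] <- suppressWarnings(as.integer(x[[col]]))
  if ("case_score" %in% names(x)) x$case_score <- suppressWarnings(as.numeric(x$case_score))
  bad <- which(x$diagnosis_date > x$enrollment_date)
  if (length(bad))
    stop_data("%s: row %d: diagnosis_date after enrollment_date", basename(path), bad[1])
  x
}

#' Read a per-clinic cost-input table
#' @param path CSV with clinic_id, n_clients, n_contacts, the three money
#'   component columns and optionally net_suppressed
#' @return a [cost_inputs()] tibble
#' @export
read_cost_inputs <- function(path) {
  x <- read_table(path, c(clinic_id = "character", n_clients = "integer",
                          n_contacts = "integer", client_costs = "money",
                          staff_costs = "money", materials_costs = "money"))
  net <- if ("net_suppressed" %in% names(x)) suppressWarnings(as.integer(x$net_suppressed)) else NA_integer_
  cost_inputs(x$clinic_id, x$n_clients, x$n_contacts,
              x$client_costs, x$staff_costs, x$materials_costs, net)
}

#' Write a table as CSV (ISO dates, money at 2 decimals)
#' @param x tibble
#' @param path output path
#' @param money_cols columns to serialize with exactly 2 decimals
#' @return `path`, invisibly
#' @export
write_table <- function(x, path, money_cols = character()) {
  for (col in intersect(money_cols, names(x))) x[[col]] <- sprintf("%.2f", x[[col]])
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
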