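# Long-format survey tables: reading, validation, de-duplication.
#
# Three kinds of field sheets are supported, mirroring a biweekly
# flowering-season survey design (sites subdivided into 1 m2 subplots,
# several sampling rounds per year):
#   flowers:  year, round, site, subplot, plant, count
#   visits:   year, round, site, subplot, plant, pollinator, visits
#   fruitset: year, site, plant, individual, flowers_marked, fruits

survey_schemas <- list(
  flowers  = list(cols = c("year", "round", "site", "subplot", "plant", "count"),
                  keys = c("year", "round", "site", "subplot", "plant"),
                  values = "count"),
  visits   = list(cols = c("year", "round", "site", "subplot", "plant", "pollinator", "visits"),
                  keys = c("year", "round", "site", "subplot", "plant", "pollinator"),
                  values = "visits"),
  fruitset = list(cols = c("year", "site", "plant", "individual", "flowers_marked", "fruits"),
                  keys = c("year", "site", "plant", "individual"),
                  values = c("flowers_marked", "fruits"))
)

survey_kinds <- names(survey_schemas)

new_survey_table <- function(x, kind) {
  x <- tibble::as_tibble(x)
  attr(x, "kind") <- kind
  class(x) <- c("survey_table", class(x))
  x
}

#' The kind of a survey table
#'
#' @param x A `survey_table`.
#' @return One of `"flowers"`, `"visits"`, `"fruitset"`.
#' @export
survey_kind <- function(x) attr(x, "kind")

#' Validate a data frame as a survey table
#'
#' Checks a long-format data frame against the schema for `kind`, coerces
#' column types, sums duplicate keys (field sheets legitimately split one
#' observation over several rows), and returns a `survey_table` tibble.
#'
#' Validation rules: counts and visits must be non-negative integers;
#' `flowers_marked >= 1`; `fruits <= flowers_marked` for every fruit-set
#' record. Violations raise an error naming the offending row.
#'
#' @param x A data frame with the columns of the given schema.
#' @param kind One of `"flowers"`, `"visits"`, `"fruitset"`.
#' @param quiet Suppress the merge-report message?
#' @return A `survey_table` tibble with one row per unique key.
#' @examples
#' df <- data.frame(year = 2020, round = 1, site = "A", subplot = 1,
#'                  plant = "Cistus", count = c(3, 4))
#' as_survey_table(df, "flowers")  # duplicate key summed to 7
#' @export
as_survey_table <- function(x, kind = survey_kinds, quiet = FALSE) {
  kind <- match.arg(kind)
  schema <- survey_schemas[[kind]]
  x <- tibble::as_tibble(x)

  missing_cols <- setdiff(schema$cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s table is missing required column(s): %s",
                  kind, paste(missing_cols, collapse = ", ")),
          class = "pollistab_schema_error")
  }
  x <- x[schema$cols]

  for (v in schema$values) {
    vals <- x[[v]]
    if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
      abort(sprintf("column '%s' must be finite and numeric", v),
            class = "pollistab_validation_error")
    }
    bad <- which(vals < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative %s at row %d", v, bad[1]),
            class = "pollistab_validation_error")
    }
  }
  if (kind == "fruitset") {
    bad <- which(x$flowers_marked < 1)
    if (length(bad) > 0) {
      abort(sprintf("flowers_marked must be >= 1 (row %d)", bad[1]),
            class = "pollistab_validation_error")
    }
    bad <- which(x$fruits > x$flowers_marked)
    if (length(bad) > 0) {
      abort(sprintf("fruits > flowers_marked at row %d", bad[1]),
            class = "pollistab_validation_error")
    }
  }

  n_in <- nrow(x)
  x <- x |>
    group_by(across(all_of(schema$keys))) |>
    summarise(across(all_of(schema$values), sum), .groups = "drop")
  n_merged <- n_in - nrow(x)
  if (n_merged > 0 && !quiet) {
    inform(sprintf("%d duplicate %s row(s) merged by summation", n_merged, kind))
  }
  new_survey_table(x, kind)
}

#' Read a survey CSV
#'
#' Reads a long-format survey CSV whose header must match the schema for
#' `kind` exactly (order-insensitive):
#' * `flowers`: `year,round,site,subplot,plant,count`
#' * `visits`: `year,round,site,subplot,plant,pollinator,visits`
#' * `fruitset`: `year,site,plant,individual,flowers_marked,fruits`
#'
#' Duplicate keys are summed and reported; invalid rows (negative counts,
#' `fruits > flowers_marked`) raise an error with the row number.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_survey_table
#' @return A `survey_table` tibble.
#' @export
read_survey_table <- function(path, kind = survey_kinds, quiet = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_survey_table(x, kind, quiet = quiet)
}

#' Write a survey table to CSV
#'
#' @param x A `survey_table`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_survey_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(unclass_survey(x)), path)
  invisible(x)
}

unclass_survey <- function(x) {
  class(x) <- setdiff(class(x), "survey_table")
  x
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("# survey_table <%s>, %d record(s)\n", survey_kind(x), nrow(x)))
  NextMethod()
}
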