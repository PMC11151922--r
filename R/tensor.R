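# Metacommunity tensors: dense unit x patch x time arrays.
#
# "Unit" depends on the system variable: a plant species (flower
# availability, fruit set), a pollinator species (visitation rate), or a
# plant-pollinator pair (interaction frequency). Patches are sites; time
# points are years. Zero-filling of unobserved (unit, site, year) cells is a
# modelling commitment: for count-like variables an absence is a true zero
# abundance for that year, so it enters the temporal SDs. Fruit set is the
# exception (see [aggregate_fruitset()]).

tensor_variables <- c("flower_availability", "visitation_rate",
                      "interaction_frequency", "fruit_set")

new_metacommunity_tensor <- function(values, variable, allow_na = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!allow_na && anyNA(values)) abort("tensor has missing cells")
  finite <- values[!is.na(values)]
  if (any(finite < 0)) abort("tensor values must be non-negative")
  if (dim(values)[3] < 2) abort("temporal dimension < 2")
  structure(values,
            variable = variable,
            class = c("metacommunity_tensor", "array"))
}

#' Build a unit x site x year tensor from a survey table
#'
#' Aggregates subplots and within-year sampling rounds to one value per
#' (unit, site, year), following the design in which all rounds and subplots
#' of a site-year are combined. The unit universe is the union of units
#' observed in *any* site-year; absent combinations are zero-filled, i.e.
#' treated as true zero abundance for that year.
#'
#' Unit definitions by variable:
#' * `flower_availability` (from a flowers table): unit = plant species;
#' * `visitation_rate` (from a visits table): unit = pollinator species,
#'   visits summed over the plants it visited;
#' * `interaction_frequency` (from a visits table): unit = the
#'   (plant, pollinator) pair.
#'
#' @param table A `survey_table` of kind `flowers` (for
#'   `flower_availability`) or `visits` (for the other two variables).
#' @param variable One of `"flower_availability"`, `"visitation_rate"`,
#'   `"interaction_frequency"`.
#' @param annualize How to combine the sampling rounds of a year: `"sum"`
#'   (default, season total) or `"mean"` (average per round over the global
#'   round universe, with unobserved rounds counting as zero).
#' @return A `metacommunity_tensor` (3-D array, unit x site x year, with
#'   dimnames and a `variable` attribute).
#' @examples
#' fl <- as_survey_table(data.frame(
#'   year = c(2020, 2021), round = 1, site = "A", subplot = 1,
#'   plant = "Cistus", count = c(2, 4)), "flowers")
#' build_tensor(fl, "flower_availability")
#' @export
build_tensor <- function(table,
                         variable = c("flower_availability", "visitation_rate",
                                      "interaction_frequency"),
                         annualize = c("sum", "mean")) {
  variable <- match.arg(variable)
  annualize <- match.arg(annualize)
  kind <- survey_kind(table)
  needed <- if (variable == "flower_availability") "flowers" else "visits"
  if (!identical(kind, needed)) {
    abort(sprintf("variable '%s' needs a '%s' table, got '%s'",
                  variable, needed, kind %||% "<unknown>"))
  }
  if (dplyr::n_distinct(table$year) < 2) abort("temporal dimension < 2")

  value_col <- survey_schemas[[kind]]$values
  n_rounds <- dplyr::n_distinct(table$round)

  x <- tibble::as_tibble(unclass_survey(table))
  x <- switch(variable,
    flower_availability = x |> mutate(unit = as.character(.data$plant)),
    visitation_rate = x |> mutate(unit = as.character(.data$pollinator)),
    interaction_frequency = x |>
      mutate(unit = paste(.data$plant, .data$pollinator, sep = ":"))
  )
  annual <- x |>
    group_by(.data$unit, site = as.character(.data$site),
             year = .data$year) |>
    summarise(value = sum(.data[[value_col]]), .groups = "drop")
  if (annualize == "mean") annual$value <- annual$value / n_rounds

  units <- sort(unique(annual$unit))
  sites <- sort(unique(annual$site))
  years <- sort(unique(annual$year))
  arr <- array(0, dim = c(length(units), length(sites), length(years)),
               dimnames = list(unit = units, patch = sites,
                               time = as.character(years)))
  arr[cbind(match(annual$unit, units), match(annual$site, sites),
            match(annual$year, years))] <- annual$value
  new_metacommunity_tensor(arr, variable)
}

#' Aggregate fruit-set records into a plant x site x year tensor
#'
#' Fruit set is fruits produced per marked flower, in `[0, 1]`. Unlike
#' abundance counts, an unmeasured fruit set is *not* zero: (plant, site,
#' year) cells with no marked individuals are flagged missing (`NA`) and
#' excluded from the partition for this variable (complete-case unit subset,
#' with a warning downstream), never zero-filled.
#'
#' @param table A `survey_table` of kind `fruitset`.
#' @param mode `"pooled"` (default): cell = total fruits / total flowers
#'   marked, a flower-weighted estimate; `"individual_mean"`: unweighted
#'   mean of the per-individual proportions.
#' @return A `metacommunity_tensor` with variable `"fruit_set"`, possibly
#'   containing `NA` cells.
#' @examples
#' fs <- as_survey_table(data.frame(
#'   year = rep(c(2020, 2021), each = 2), site = "A", plant = "Cistus",
#'   individual = 1:4, flowers_marked = c(20, 5, 10, 10),
#'   fruits = c(10, 1, 4, 6)), "fruitset")
#' aggregate_fruitset(fs)[,,]            # 2020: 11/25 = 0.44
#' aggregate_fruitset(fs, "individual_mean")[,,]  # 2020: (0.5 + 0.2)/2
#' @export
aggregate_fruitset <- function(table, mode = c("pooled", "individual_mean")) {
  mode <- match.arg(mode)
  if (!identical(survey_kind(table), "fruitset")) {
    abort("aggregate_fruitset() needs a 'fruitset' table")
  }
  if (nrow(table) == 0) abort("empty fruit-set table")
  if (dplyr::n_distinct(table$year) < 2) abort("temporal dimension < 2")

  cells <- tibble::as_tibble(unclass_survey(table)) |>
    group_by(unit = as.character(.data$plant),
             site = as.character(.data$site), year = .data$year) |>
    summarise(value = if (mode == "pooled") {
      sum(.data$fruits) / sum(.data$flowers_marked)
    } else {
      mean(.data$fruits / .data$flowers_marked)
    }, .groups = "drop")

  units <- sort(unique(cells$unit))
  sites <- sort(unique(cells$site))
  years <- sort(unique(cells$year))
  arr <- array(NA_real_, dim = c(length(units), length(sites), length(years)),
               dimnames = list(unit = units, patch = sites,
                               time = as.character(years)))
  arr[cbind(match(cells$unit, units), match(cells$site, sites),
            match(cells$year, years))] <- cells$value
  new_metacommunity_tensor(arr, "fruit_set", allow_na = TRUE)
}

#' @export
print.metacommunity_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("# metacommunity_tensor <%s>: %d unit(s) x %d patch(es) x %d time point(s)\n",
              attr(x, "variable"), d[1], d[2], d[3]))
  if (anyNA(x)) cat(sprintf("# %d missing cell(s)\n", sum(is.na(x))))
  print(unclass(x)[, , , drop = FALSE], ...)
  invisible(x)
}

#' Convert a metacommunity tensor to a tidy tibble
#'
#' @param x A `metacommunity_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `unit`, `patch`, `time`, `value` (missing
#'   cells omitted).
#' @export
as_tibble.metacommunity_tensor <- function(x, ...) {
  out <- as.data.frame.table(unclass(x), responseName = "value",
                             stringsAsFactors = FALSE)
  names(out)[1:3] <- c("unit", "patch", "time")
  tibble::as_tibble(out) |>
    filter(!is.na(.data$value)) |>
    arrange(.data$unit, .data$patch, .data$time)
}
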