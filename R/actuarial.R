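#' Total medical expenditure of a projected population
#'
#' Actuarial aggregation: for every year (and age group) the total
#' expenditure of state j is the projected head count times the
#' per-capita expenditure of that state. Death-state rows contribute
#' nothing and are excluded.
#'
#' Two bases are exposed. `"published_monthly"` multiplies annual head
#' counts by the MONTHLY individual per-capita values; this is the
#' arithmetic that reproduces the published total-expenditure series
#' (verified by direct multiplication of the published 2035 counts and
#' per-capita table) and is kept for compatibility. `"annual"`
#' (12 x monthly) is the economically meaningful convention for new
#' analyses; `"family_annual"` uses the family-level annual values.
#'
#' @param series `projection_series` tibble (`year`, `age_group`,
#'   `state`, `count`).
#' @param table [as_expenditure_table()] tibble; if it carries
#'   `age_group`, totals are computed per age band, otherwise pooled
#'   per-state values are applied to every row.
#' @param basis `"published_monthly"`, `"annual"` or `"family_annual"`.
#' @return A `forecast_result` tibble: `year`, `age_group`, `state`,
#'   `population`, `per_capita`, `basis`, `total_yuan`, `total_billions`.
#' @examples
#' pop <- fixture_populations_2035()
#' total_expenditure(pop, fixture_expenditure())
#' @export
total_expenditure <- function(series, table,
                              basis = c("published_monthly", "annual",
                                        "family_annual")) {
  basis <- match.arg(basis)
  table <- as_expenditure_table(table)
  ser <- tibble::as_tibble(series) |>
    dplyr::filter(.data$state %in% transient_states())
  if (!"age_group" %in% names(ser)) ser$age_group <- "all"
  # avoid double counting when both stratified and pooled rows are present
  if (dplyr::n_distinct(ser$age_group) > 1 && "all" %in% ser$age_group) {
    ser <- dplyr::filter(ser, .data$age_group != "all")
  }
  per_capita_col <- switch(basis,
    published_monthly = "individual_monthly",
    annual = "individual_monthly",
    family_annual = "family_annual")
  if (!per_capita_col %in% names(table)) {
    abort(sprintf("expenditure table lacks the '%s' column needed for basis '%s'",
                  per_capita_col, basis))
  }
  tab <- dplyr::select(table, dplyr::any_of(c("age_group", "state")),
                       per_capita = dplyr::all_of(per_capita_col))
  if (basis == "annual") tab$per_capita <- annualize_monthly(tab$per_capita)
  by_age <- "age_group" %in% names(tab)
  missing_states <- setdiff(unique(ser$state), unique(tab$state))
  if (length(missing_states) > 0) {
    abort(sprintf("expenditure table has no state-%d value", missing_states[1]))
  }
  joined <- dplyr::inner_join(ser, tab,
                              by = if (by_age) c("age_group", "state")
                                   else "state")
  if (by_age && nrow(joined) < nrow(ser)) {
    abort("expenditure table does not cover every age group in the series")
  }
  out <- joined |>
    dplyr::mutate(population = .data$count,
                  basis = basis,
                  total_yuan = .data$population * .data$per_capita,
                  total_billions = .data$total_yuan / 1e9) |>
    dplyr::select("year", "age_group", "state", "population", "per_capita",
                  "basis", "total_yuan", "total_billions") |>
    dplyr::arrange(.data$year, .data$age_group, .data$state)
  class(out) <- c("forecast_result", class(tibble::tibble()))
  out
}

#' Coerce published total-expenditure values to a forecast result
#'
#' Builds a `forecast_result` directly from totals (billions of yuan),
#' e.g. published anchor values, with no population/per-capita split.
#'
#' @param df Tibble with `year`, `age_group`, `state`, `total_billion`.
#' @param basis Basis label recorded on the result.
#' @return A `forecast_result` tibble.
#' @export
as_forecast_result <- function(df, basis = "published_monthly") {
  stopifnot(all(c("year", "state", "total_billion") %in% names(df)))
  out <- tibble::as_tibble(df) |>
    dplyr::mutate(age_group = if ("age_group" %in% names(df))
                    .data$age_group else "all",
                  population = NA_real_, per_capita = NA_real_,
                  basis = basis,
                  total_yuan = .data$total_billion * 1e9,
                  total_billions = .data$total_billion) |>
    dplyr::select("year", "age_group", "state", "population", "per_capita",
                  "basis", "total_yuan", "total_billions")
  class(out) <- c("forecast_result", class(tibble::tibble()))
  out
}

result_total <- function(result, year, state, age_group = NULL) {
  rows <- dplyr::filter(tibble::as_tibble(result), .data$year == !!year,
                        .data$state == !!state)
  if (nrow(rows) == 0) {
    abort(sprintf("no totals for year %s, state %s", year, state))
  }
  if (!is.null(age_group)) {
    rows <- dplyr::filter(rows, .data$age_group == !!age_group)
    if (nrow(rows) == 0) {
      abort(sprintf("no totals for age group '%s' in year %s", age_group, year))
    }
  } else if (dplyr::n_distinct(rows$age_group) > 1 &&
             "all" %in% rows$age_group) {
    rows <- dplyr::filter(rows, .data$age_group != "all")
  }
  sum(rows$total_yuan)
}

#' Expenditure gap between two health states in one year
#'
#' `total(state_a) - total(state_b)` in yuan for the given year.
#'
#' @param result A `forecast_result`.
#' @param year Calendar year.
#' @param state_a,state_b Health states (1-4).
#' @param age_group Optional age band; default pools across bands.
#' @return Difference in yuan.
#' @export
expenditure_gap <- function(result, year, state_a, state_b,
                            age_group = NULL) {
  result_total(result, year, state_a, age_group) -
    result_total(result, year, state_b, age_group)
}

#' Expenditure change between two forecast results
#'
#' `total in result_t2 - total in result_t1` for one state (and
#' optionally one age band). Each result must hold a single year, and the
#' two results must share the same basis (units).
#'
#' @param result_t1,result_t2 `forecast_result` objects, one year each.
#' @param state Health state (1-4).
#' @param age_group Optional age band.
#' @return Difference in yuan.
#' @export
expenditure_change <- function(result_t1, result_t2, state,
                               age_group = NULL) {
  b1 <- unique(result_t1$basis)
  b2 <- unique(result_t2$basis)
  if (!identical(b1, b2)) {
    abort(sprintf("basis mismatch between results ('%s' vs '%s')", b1, b2))
  }
  y1 <- unique(result_t1$year)
  y2 <- unique(result_t2$year)
  if (length(y1) != 1 || length(y2) != 1) {
    abort("each result must contain exactly one year")
  }
  result_total(result_t2, y2, state, age_group) -
    result_total(result_t1, y1, state, age_group)
}

#' Write a forecast report CSV
#'
#' Internally totals are in yuan; the report adds a billions column at
#' three decimal places. Rows are ordered deterministically by year, age
#' group, state.
#'
#' @param result A `forecast_result`.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
render_report <- function(result, path) {
  if (nrow(result) == 0) abort("empty forecast result")
  out <- tibble::as_tibble(result) |>
    dplyr::arrange(.data$year, .data$age_group, .data$state) |>
    dplyr::mutate(total_billions = sprintf("%.3f", .data$total_yuan / 1e9))
  readr::write_csv(out, path)
  invisible(out)
}

#' Plot a forecast result
#'
#' @param object A `forecast_result`.
#' @param ... Unused.
#' @return A ggplot of total expenditure (billions of yuan) by state over
#'   time.
#' @export
autoplot.forecast_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (dplyr::n_distinct(df$age_group) > 1 && "all" %in% df$age_group) {
    df <- dplyr::filter(df, .data$age_group == "all")
  }
  df$state_label <- factor(state_labels()[as.character(df$state)],
                           levels = unname(state_labels()[1:4]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$total_billions,
                                   colour = .data$state_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "year", y = "total expenditure (billions of yuan)",
                  colour = "health state") +
    ggplot2::theme_minimal()
}
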