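#' Exogenous new-entrants schedule
#'
#' People turning 60 join the projected population each calendar year.
#' The schedule gives per-year entrant counts and the health-state
#' distribution they arrive with (default: the observed baseline
#' transient-state shares of the bundled fixture, which already sum to 1).
#'
#' @param years Integer vector of calendar years.
#' @param counts Non-negative entrant counts, one per year.
#' @param state_shares Length-4 distribution over states 1-4 at entry.
#' @return An `entrants_schedule` tibble (`year`, `entrant_count`) with a
#'   `state_shares` attribute.
#' @export
entrants_schedule <- function(years, counts,
                              state_shares = c(0.1215, 0.2982, 0.3849,
                                               0.1954)) {
  if (length(years) != length(counts)) abort("years and counts differ in length")
  if (any(counts < 0)) abort("entrant counts must be >= 0")
  if (length(state_shares) != 4 || any(state_shares < 0) ||
      abs(sum(state_shares) - 1) > 1e-6) {
    abort("state_shares must be 4 non-negative values summing to 1")
  }
  out <- tibble::tibble(year = as.integer(years),
                        entrant_count = as.numeric(counts)) |>
    dplyr::arrange(.data$year)
  attr(out, "state_shares") <- state_shares
  class(out) <- c("entrants_schedule", class(tibble::tibble()))
  out
}

#' @rdname entrants_schedule
#' @param path CSV with columns `year`, `entrant_count` and optional
#'   `share_s1..share_s4`.
#' @export
read_entrants <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  shares <- c(0.1215, 0.2982, 0.3849, 0.1954)
  sh_cols <- paste0("share_s", 1:4)
  if (all(sh_cols %in% names(df))) {
    shares <- as.numeric(df[1, sh_cols])
    df <- df[, setdiff(names(df), sh_cols)]
  }
  entrants_schedule(df$year, df$entrant_count, state_shares = shares)
}

#' Project the elderly population by health state
#'
#' Advances per-age-group health-state population vectors in two-year
#' steps through the group's transition matrix (Chapman-Kolmogorov
#' composition over steps), with fractional aging across five-year bands,
#' an absorbing cumulative-death state, and exogenous new entrants into
#' the youngest band. Annual values between step grid points are linearly
#' interpolated.
#'
#' Aging uses the uniform-within-band approximation: after each two-year
#' transition, 2/5 of each band's living population moves to the next
#' band (the open-ended oldest band retains everyone).
#'
#' @param base Tibble `year`, `age_group`, `state`, `count` for the base
#'   year (state 5 rows optional, default 0). Use `age_group = "all"`
#'   with a single overall matrix for an unstratified projection.
#' @param matrices A single [transition_matrix()] (applied to every
#'   group) or a named list keyed by the base's age-group labels.
#' @param entrants An [entrants_schedule()] covering every calendar year
#'   after the base year up to the horizon, or `NULL` for no entrants.
#' @param horizon Final calendar year of the projection.
#' @param aging `"fractional"` (default) or `"none"`.
#' @param annual If `TRUE`, interpolate the biennial grid to annual
#'   values; otherwise return grid years only.
#' @return A `projection_series` tibble (`year`, `age_group`, `state`,
#'   `count`) including pooled `age_group = "all"` rows when stratified,
#'   with a `provenance` attribute.
#' @examples
#' base <- fixture_populations_2015_by_age()
#' series <- project_cohorts(base, fixture_transition_by_age(),
#'                           horizon = 2021)
#' @export
project_cohorts <- function(base, matrices, entrants = NULL, horizon,
                            aging = c("fractional", "none"),
                            annual = TRUE) {
  aging <- match.arg(aging)
  stopifnot(all(c("year", "age_group", "state", "count") %in% names(base)))
  base_year <- unique(base$year)
  if (length(base_year) != 1) abort("base population must be a single year")
  if (horizon <= base_year) abort("horizon must be after the base year")
  groups <- sort(unique(as.character(base$age_group)))  # youngest band first
  stratified <- !identical(groups, "all")
  if (is_transition_matrix(matrices)) {
    matrices <- setNames(rep(list(matrices), length(groups)), groups)
  }
  missing_m <- setdiff(groups, names(matrices))
  if (length(missing_m) > 0) {
    abort(sprintf("no transition matrix for age group '%s'", missing_m[1]))
  }
  step_years <- attr(matrices[[groups[1]]], "period_years") %||% 2
  n_steps <- ceiling((horizon - base_year) / step_years)
  grid_years <- base_year + step_years * (0:n_steps)

  if (!is.null(entrants)) {
    needed <- seq(base_year + 1, grid_years[length(grid_years)])
    gap <- setdiff(needed, entrants$year)
    if (length(gap) > 0) {
      abort(sprintf("entrants schedule has no row for year %d", gap[1]))
    }
    shares <- attr(entrants, "state_shares")
  }

  # state vectors: groups x 5, deaths accumulate in column 5
  v <- matrix(0, length(groups), 5, dimnames = list(groups, 1:5))
  for (r in seq_len(nrow(base))) {
    v[as.character(base$age_group[r]), base$state[r]] <- base$count[r]
  }
  snapshots <- vector("list", n_steps + 1)
  snapshots[[1]] <- v
  for (k in seq_len(n_steps)) {
    for (g in groups) v[g, ] <- propagate(v[g, ], matrices[[g]])
    if (aging == "fractional" && stratified && length(groups) > 1) {
      frac <- step_years / 5
      moves <- v[, 1:4, drop = FALSE] * frac
      for (gi in seq_len(length(groups) - 1)) {
        v[gi, 1:4] <- v[gi, 1:4] - moves[gi, ]
        v[gi + 1, 1:4] <- v[gi + 1, 1:4] + moves[gi, ]
      }
    }
    if (!is.null(entrants)) {
      yrs <- (grid_years[k] + 1):grid_years[k + 1]
      inflow <- sum(entrants$entrant_count[entrants$year %in% yrs])
      v[1, 1:4] <- v[1, 1:4] + inflow * shares
    }
    snapshots[[k + 1]] <- v
  }

  grid <- purrr::map_dfr(seq_along(snapshots), function(k) {
    m <- snapshots[[k]]
    tibble::tibble(year = grid_years[k],
                   age_group = rep(rownames(m), times = 5),
                   state = rep(1:5, each = nrow(m)),
                   count = as.vector(m))
  })
  if (stratified) {
    pooled <- grid |>
      dplyr::group_by(.data$year, .data$state) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(age_group = "all")
    grid <- dplyr::bind_rows(grid, pooled)
  }
  out <- grid
  if (annual && step_years > 1) {
    out <- grid |>
      dplyr::group_by(.data$age_group, .data$state) |>
      dplyr::reframe({
        yrs <- seq(min(.data$year), max(.data$year))
        ap <- stats::approx(.data$year, .data$count, xout = yrs)
        tibble::tibble(year = yrs, count = ap$y)
      }) |>
      dplyr::select("year", "age_group", "state", "count")
  }
  out <- dplyr::filter(out, .data$year <= horizon) |>
    dplyr::arrange(.data$year, .data$age_group, .data$state)
  structure(out,
            provenance = list(base_year = base_year, horizon = horizon,
                              aging = aging, step_years = step_years,
                              matrices = names(matrices),
                              entrants = !is.null(entrants)),
            class = c("projection_series", class(tibble::tibble())))
}

#' Read and write projection series CSVs
#'
#' Long format: `year`, `age_group`, `state`, `count`.
#'
#' @param series A `projection_series` (or compatible tibble).
#' @param path File path.
#' @return `write_series()` returns `path` invisibly; `read_series()` a
#'   validated `projection_series` tibble.
#' @export
write_series <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          year = readr::col_integer(),
                          age_group = readr::col_character(),
                          state = readr::col_integer(),
                          count = readr::col_double()))
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  check_states(df$state)
  if (any(df$count < 0)) abort("negative population count in series file")
  class(df) <- c("projection_series", class(tibble::tibble()))
  df
}

#' Plot a projection series
#'
#' @param object A `projection_series`.
#' @param ... Unused.
#' @return A ggplot of living-state population counts over time, faceted
#'   by age group.
#' @export
autoplot.projection_series <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$state %in% transient_states())
  df$state_label <- factor(state_labels()[as.character(df$state)],
                           levels = unname(state_labels()[1:4]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$count / 1e6,
                                   colour = .data$state_label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~age_group, scales = "free_y") +
    ggplot2::labs(x = "year", y = "population (millions)",
                  colour = "health state") +
    ggplot2::theme_minimal()
}
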