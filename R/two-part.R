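#' Fit the two-part medical expenditure model
#'
#' Part 1 is a probit for whether any expenditure occurs; part 2 is a
#' linear (level-scale, yuan) regression of expenditure on the same
#' covariates over the positive observations. The joint likelihood
#' factorizes over the two parts, so the separate probit MLE and OLS fit
#' are jointly the maximum-likelihood estimate; the combined
#' log-likelihood is reported (probit terms plus normal density terms at
#' the MLE residual scale).
#'
#' @param panel Panel tibble with the outcome column, `state` and the
#'   covariates. Death-state rows and rows with a missing outcome are
#'   dropped.
#' @param outcome `"individual_monthly"` or `"family_annual"`.
#' @param covariates Covariate column names entering both parts.
#' @param include_state If `TRUE` (default) the numeric self-rated health
#'   state enters both parts, mirroring the published regressions in
#'   which worse health raises both participation and spending.
#' @return A `two_part_fit` with components `participation` (probit glm),
#'   `level` (lm on positives), `residual_sd` (MLE sigma, yuan),
#'   `outcome`, `n_used`, `n_positive`, `log_likelihood`.
#' @examples
#' p1 <- generate_baseline(n = 500, seed = 2)
#' p1 <- simulate_expenditure(p1, truth_from_kernel(fixture_transition_overall()))
#' fit <- fit_two_part(p1, "individual_monthly")
#' glance(fit)
#' @export
fit_two_part <- function(panel, outcome = c("individual_monthly",
                                            "family_annual"),
                         covariates = character(), include_state = TRUE) {
  outcome <- match.arg(outcome)
  col <- paste0(outcome, "_expenditure")
  if (!col %in% names(panel)) abort(sprintf("panel lacks column '%s'", col))
  dat <- dplyr::filter(panel, .data$state %in% transient_states(),
                       !is.na(.data[[col]]))
  if (nrow(dat) == 0) abort("no usable observations for the outcome")
  y <- dat[[col]]
  if (any(y < 0)) abort("negative expenditure in panel")
  pos <- y > 0
  if (all(pos) || all(!pos)) {
    abort("outcome is all-zero or all-positive; the two-part model is unidentified")
  }
  terms <- c(if (include_state) "state", covariates)
  if (length(terms) == 0) terms <- "1"
  fml1 <- stats::as.formula(paste("pos ~", paste(terms, collapse = " + ")))
  fml2 <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  d1 <- dplyr::mutate(dat, pos = as.integer(pos), y = y)
  part1 <- glm(fml1, data = d1, family = binomial("probit"))
  d2 <- dplyr::filter(d1, .data$pos == 1L)
  part2 <- lm(fml2, data = d2)
  n_pos <- nrow(d2)
  sigma <- sqrt(sum(stats::residuals(part2)^2) / n_pos)
  # a degenerate (perfect-fit) level part leaves only the probit terms
  ll <- as.numeric(stats::logLik(part1)) +
    if (sigma > 1e-12) sum(dnorm(stats::residuals(part2), 0, sigma,
                                 log = TRUE)) else 0
  structure(
    list(participation = part1, level = part2, residual_sd = sigma,
         outcome = outcome, covariate_names = covariates,
         include_state = include_state, n_used = nrow(dat),
         n_positive = n_pos, log_likelihood = ll),
    class = "two_part_fit")
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat(sprintf("<two_part_fit> outcome = %s, n = %d (%d positive), sigma = %.1f\n",
              x$outcome, x$n_used, x$n_positive, x$residual_sd))
  cat("participation (probit):\n")
  print(round(coef(x$participation), 4))
  cat("level (yuan):\n")
  print(round(coef(x$level), 2))
  invisible(x)
}

#' Expected expenditure at a covariate profile
#'
#' The unconditional two-part mean `Phi(x . delta1) * max(x . delta2, 0)`:
#' participation probability times the (floored) conditional level.
#'
#' @param fit A [fit_two_part()] result.
#' @param profile Named list or data frame (any number of rows) covering
#'   all model covariates.
#' @return Numeric vector of expected expenditure in yuan, one per
#'   profile row; always non-negative.
#' @export
expected_expenditure <- function(fit, profile) {
  stopifnot(inherits(fit, "two_part_fit"))
  nd <- if (is.data.frame(profile)) tibble::as_tibble(profile)
        else tibble::as_tibble(as.list(profile))
  needed <- c(if (fit$include_state) "state", fit$covariate_names)
  missing_cov <- setdiff(needed, names(nd))
  if (length(missing_cov) > 0) {
    abort(sprintf("profile lacks covariate '%s'", missing_cov[1]))
  }
  p <- predict(fit$participation, newdata = nd, type = "response")
  mu <- pmax(predict(fit$level, newdata = nd), 0)
  as.numeric(p * mu)
}

#' Per-state (and per-age-band) fitted expenditure table
#'
#' For each transient state (optionally crossed with age band), averages
#' the fitted expected expenditure over the covariate rows of the panel
#' members in that cell, for both the family-annual and
#' individual-monthly fits. Empty cells come back as `NA` (flagged via
#' the `flagged` attribute), never as zero.
#'
#' @param panel Panel tibble with `state`, `age` and covariates.
#' @param fit_family Two-part fit for the family-annual outcome (or
#'   `NULL` to skip that column).
#' @param fit_individual Two-part fit for the individual-monthly outcome
#'   (or `NULL`).
#' @param by_age If `TRUE`, stratify by [age_to_group()] bands.
#' @return An `expenditure_table` tibble: optional `age_group`, `state`,
#'   `family_annual`, `individual_monthly` (yuan).
#' @export
per_state_expenditure <- function(panel, fit_family = NULL,
                                  fit_individual = NULL, by_age = FALSE) {
  if (is.null(fit_family) && is.null(fit_individual)) {
    abort("supply at least one two_part_fit")
  }
  dat <- dplyr::filter(panel, .data$state %in% transient_states())
  if (by_age) dat$age_group <- as.character(age_to_group(dat$age))
  keys <- if (by_age) c("age_group", "state") else "state"
  grid <- if (by_age) {
    tidyr::expand_grid(age_group = age_group_labels(), state = transient_states())
  } else {
    tibble::tibble(state = transient_states())
  }
  cell_mean <- function(fit, rows) {
    if (is.null(fit) || nrow(rows) == 0) return(NA_real_)
    mean(expected_expenditure(fit, rows))
  }
  fam <- ind <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    rows <- dat[dat$state == grid$state[k], , drop = FALSE]
    if (by_age) rows <- rows[rows$age_group == grid$age_group[k], , drop = FALSE]
    fam[k] <- cell_mean(fit_family, rows)
    ind[k] <- cell_mean(fit_individual, rows)
  }
  out <- dplyr::mutate(grid, family_annual = fam, individual_monthly = ind)
  if (is.null(fit_family)) out$family_annual <- NULL
  if (is.null(fit_individual)) out$individual_monthly <- NULL
  flagged <- out |>
    dplyr::filter(dplyr::if_all(dplyr::any_of(c("family_annual",
                                                "individual_monthly")),
                                is.na))
  res <- as_expenditure_table(out)
  attr(res, "flagged") <- flagged[keys]
  res
}

#' Coerce a data frame to an expenditure table
#'
#' @param df Data frame with `state` (1-4), at least one of
#'   `family_annual` / `individual_monthly` (yuan, non-negative), and an
#'   optional `age_group` column.
#' @return An `expenditure_table` tibble.
#' @export
as_expenditure_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"state" %in% names(df)) abort("expenditure table needs a 'state' column")
  check_states(df$state[!is.na(df$state)], allow_death = FALSE)
  vals <- intersect(c("family_annual", "individual_monthly"), names(df))
  if (length(vals) == 0) {
    abort("expenditure table needs family_annual and/or individual_monthly")
  }
  for (v in vals) {
    if (any(df[[v]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative expenditure in column '%s'", v))
    }
  }
  class(df) <- c("expenditure_table", class(tibble::tibble()))
  df
}

#' Convert a monthly per-capita expenditure to an annual one
#'
#' Assumes a stable average monthly spend: the annual value is exactly
#' twelve times the monthly one.
#'
#' @param value Monthly expenditure in yuan (non-negative).
#' @return `value * 12`, yuan per year.
#' @examples
#' annualize_monthly(647.86)  # 7774.32
#' @export
annualize_monthly <- function(value) {
  if (any(value < 0, na.rm = TRUE)) abort("monthly expenditure must be >= 0")
  value * 12
}

#' Relative expenditure gap between the worst and best health states
#'
#' The "times higher" statistic: `value(state 4) / value(state 1) - 1`,
#' computed for each expenditure measure present in the table.
#'
#' @param table An [as_expenditure_table()] tibble without age
#'   stratification (or filtered to one band).
#' @param digits Rounding applied to the reported statistic (2 decimal
#'   places by convention); use `NA` for no rounding.
#' @return Tibble with `measure`, `state1`, `state4`, `times_higher`.
#' @export
expenditure_ratios <- function(table, digits = 2) {
  if ("age_group" %in% names(table) &&
      dplyr::n_distinct(table$age_group) > 1) {
    abort("expenditure_ratios expects a single (unstratified) table")
  }
  vals <- intersect(c("family_annual", "individual_monthly"), names(table))
  purrr::map_dfr(vals, function(v) {
    v1 <- table[[v]][table$state == 1]
    v4 <- table[[v]][table$state == 4]
    if (length(v1) != 1 || length(v4) != 1 || is.na(v1) || is.na(v4)) {
      abort(sprintf("'%s' must have values for states 1 and 4", v))
    }
    if (v1 == 0) abort(sprintf("'%s' state-1 value is zero (division by zero)", v))
    r <- v4 / v1 - 1
    tibble::tibble(measure = v, state1 = v1, state4 = v4,
                   times_higher = if (is.na(digits)) r else round(r, digits))
  })
}

#' Tidy the coefficients of a two-part fit
#'
#' @param x A `two_part_fit`.
#' @param ... Unused.
#' @return Tibble with `part` (participation/level), `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.two_part_fit <- function(x, ...) {
  s1 <- summary(x$participation)$coefficients
  s2 <- summary(x$level)$coefficients
  dplyr::bind_rows(
    tibble::tibble(part = "participation", term = rownames(s1),
                   estimate = s1[, 1], std.error = s1[, 2]),
    tibble::tibble(part = "level", term = rownames(s2),
                   estimate = s2[, 1], std.error = s2[, 2]))
}

#' @export
glance.two_part_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n_used,
                 n_positive = x$n_positive, residual_sd = x$residual_sd,
                 logLik = x$log_likelihood)
}
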