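#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages. Any subset can be
#' overridden by the `config` argument of [run_pipeline()]; unspecified
#' keys keep their defaults. `seed` drives every stochastic stage.
#'
#' @param seed Integer seed.
#' @return Named list of stage parameter lists.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n = 5487L,
      age_range = c(60, 89),
      state_distribution = c(0.1215, 0.2982, 0.3849, 0.1954)
    ),
    transitions = list(mode = "multinomial", covariates = character(),
                       by_age = FALSE),
    expenditure = list(covariates = character(), by_age = FALSE),
    project = list(horizon = 2035L, aging = "fractional",
                   use_fitted_matrix = FALSE),
    forecast = list(basis = "published_monthly")
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full simulation-to-forecast pipeline
#'
#' Executes, in order: synthetic panel generation (two waves plus
#' expenditures from a known truth), transition-matrix estimation,
#' two-part expenditure fitting, Chapman-Kolmogorov population
#' projection, and actuarial aggregation. Every intermediate artifact is
#' written under `out_dir`; the run is deterministic for a fixed seed.
#'
#' The projection stage starts from the bundled base-year (2015)
#' population with the bundled age-specific matrices (or, when
#' `project$use_fitted_matrix` is `TRUE`, the matrix fitted on the
#' synthetic panel applied to all groups) and the bundled demo entrants
#' schedule.
#'
#' @param config Named list (merged over [default_config()]) or a path
#'   to a YAML file with the same structure.
#' @param out_dir Output directory, created if needed.
#' @return List with the fitted objects, the artifact paths and the
#'   config used.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("eldercast_run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    panel = file.path(out_dir, "panel.csv"),
    matrix_dir = file.path(out_dir, "matrices"),
    exptable = file.path(out_dir, "exptable.csv"),
    series = file.path(out_dir, "series.csv"),
    forecast = file.path(out_dir, "forecast.csv"))
  dir.create(paths$matrix_dir, showWarnings = FALSE)

  # stage 1: simulate -------------------------------------------------
  set.seed(cfg$seed)
  truth <- truth_from_kernel(fixture_transition_overall())
  w1 <- generate_baseline(n = cfg$simulate$n,
                          age_range = cfg$simulate$age_range,
                          state_distribution = cfg$simulate$state_distribution)
  w2 <- simulate_wave2(w1, truth)
  w1 <- simulate_expenditure(w1, truth, outcome = "individual_monthly")
  fam_truth <- truth
  fam_truth$level <- c(`(Intercept)` = 1800, state = 1300)
  fam_truth$residual_sd <- 900
  w1b <- simulate_expenditure(w1, fam_truth, outcome = "family_annual")
  w1$family_annual_expenditure <- w1b$family_annual_expenditure
  panel <- dplyr::bind_rows(w1, w2)
  write_panel(panel, paths$panel)

  # stage 2: fit transitions ------------------------------------------
  fit_tr <- fit_transition_model(panel,
                                 covariates = cfg$transitions$covariates,
                                 parameterization = cfg$transitions$mode)
  P_hat <- predict_transition_matrix(fit_tr)
  write_transition_matrix(P_hat, file.path(paths$matrix_dir, "overall.csv"))
  if (isTRUE(cfg$transitions$by_age)) {
    strat <- stratified_matrices(panel)
    for (lab in names(strat)) {
      write_transition_matrix(strat[[lab]],
        file.path(paths$matrix_dir,
                  paste0(gsub("[^0-9a-z]+", "_", lab), ".csv")))
    }
  }

  # stage 3: fit expenditure ------------------------------------------
  fit_ind <- fit_two_part(w1, "individual_monthly",
                          covariates = cfg$expenditure$covariates)
  fit_fam <- fit_two_part(w1, "family_annual",
                          covariates = cfg$expenditure$covariates)
  exptable <- per_state_expenditure(w1, fit_family = fit_fam,
                                    fit_individual = fit_ind,
                                    by_age = cfg$expenditure$by_age)
  readr::write_csv(exptable, paths$exptable)

  # stage 4: project ---------------------------------------------------
  base <- fixture_populations_2015_by_age()
  matrices <- if (isTRUE(cfg$project$use_fitted_matrix)) P_hat
              else fixture_transition_by_age()
  entrants <- read_entrants(eldercast_fixture("entrants_demo.csv"))
  series <- project_cohorts(base, matrices, entrants = entrants,
                            horizon = cfg$project$horizon,
                            aging = cfg$project$aging)
  write_series(series, paths$series)

  # stage 5: forecast expenditure --------------------------------------
  result <- total_expenditure(series, exptable, basis = cfg$forecast$basis)
  render_report(result, paths$forecast)

  list(config = cfg, paths = paths, truth = truth, panel = panel,
       transition_fit = fit_tr, transition_matrix = P_hat,
       expenditure_fits = list(individual = fit_ind, family = fit_fam),
       expenditure_table = exptable, series = series, forecast = result)
}

#' Reproduce the published downstream arithmetic from bundled fixtures
#'
#' Recomputes, through the package's own operations, every checkable
#' quantity implied by the bundled published tables: one-step propagation
#' of the baseline state shares, the monthly-to-annual per-capita
#' conversions, the worst-vs-best "times higher" ratios, the 2035
#' per-state expenditure totals and their state 4 vs state 1 gap, and the
#' 2015-to-2035 per-age-band very-unhealthy expenditure changes. Each
#' computed value is compared with its published anchor at a stated
#' tolerance.
#'
#' @param out_dir Optional directory; when given, the check table is
#'   written there as `reproduction_report.csv`.
#' @return Tibble with `check`, `computed`, `published`, `tolerance`,
#'   `pass`.
#' @export
reproduce_published <- function(out_dir = NULL) {
  shares <- fixture_state_shares()
  P <- fixture_transition_overall()
  exp_tab <- fixture_expenditure()
  anchors <- fixture_forecast_anchors()
  anchor <- function(yr, grp, st) {
    anchors$total_billion[anchors$year == yr & anchors$age_group == grp &
                            anchors$state == st]
  }

  checks <- list()
  add <- function(check, computed, published, tolerance) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, computed = computed, published = published,
      tolerance = tolerance)
  }

  # one-step propagation of 2011 shares vs observed 2013 state-1 share
  prop <- propagate(shares$share_2011_pct[1:4] / 100, P)
  add("one-step state-1 share (%)", 100 * prop[1],
      shares$share_2013_pct[1], 0.1)

  # monthly -> annual per-capita conversions
  ann4 <- annualize_monthly(exp_tab$individual_monthly[exp_tab$state == 4])
  ann3 <- annualize_monthly(exp_tab$individual_monthly[exp_tab$state == 3])
  add("state-4 annual individual per-capita (yuan)", ann4, 7774.32, 1e-9)
  add("state-3 annual individual per-capita (yuan)", ann3, 3791.88, 1e-9)

  # times-higher ratios
  ratios <- expenditure_ratios(exp_tab)
  add("family times-higher ratio",
      ratios$times_higher[ratios$measure == "family_annual"], 1.27, 0.005)
  add("individual times-higher ratio",
      ratios$times_higher[ratios$measure == "individual_monthly"], 2.64, 0.005)

  # 2035 totals and gap under the published-compatible basis
  res35 <- total_expenditure(fixture_populations_2035(), exp_tab,
                             basis = "published_monthly")
  for (st in c(1, 2, 3, 4)) {
    add(sprintf("2035 state-%d total (billions)", st),
        result_total(res35, 2035, st) / 1e9, anchor(2035, "all", st), 0.01)
  }
  add("2035 state-4 vs state-1 gap (billions)",
      expenditure_gap(res35, 2035, 4, 1) / 1e9, 38.088, 0.01)

  # per-age-band very-unhealthy changes 2015 -> 2035 from anchors
  r15 <- as_forecast_result(dplyr::filter(anchors, .data$year == 2015,
                                          .data$age_group != "all"))
  r35 <- as_forecast_result(dplyr::filter(anchors, .data$year == 2035,
                                          .data$age_group != "all"))
  published_changes <- c(`65-69` = 6.111, `70-74` = 6.487, `75-79` = 3.692,
                         `80+` = 3.55)
  for (grp in names(published_changes)) {
    add(sprintf("%s state-4 change 2015-2035 (billions)", grp),
        expenditure_change(r15, r35, state = 4, age_group = grp) / 1e9,
        published_changes[[grp]], 0.001)
  }

  out <- dplyr::bind_rows(checks) |>
    dplyr::mutate(pass = abs(.data$computed - .data$published) <=
                    .data$tolerance + 1e-12)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(out, file.path(out_dir, "reproduction_report.csv"))
  }
  out
}
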