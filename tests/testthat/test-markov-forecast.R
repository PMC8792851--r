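test_that("n-step matrices obey the Chapman-Kolmogorov composition rule", {
  P <- fixture_transition_overall()
  expect_equal(unclass(n_step_matrix(P, 1)), unclass(P), tolerance = 1e-12)
  expect_equal(unname(unclass(n_step_matrix(P, 0))), diag(5),
               ignore_attr = TRUE)

  # brute-force two-step oracle
  brute <- unclass(P) %*% unclass(P)
  expect_lt(max(abs(unclass(n_step_matrix(P, 2)) - brute)), 1e-12)

  # semigroup property on random stochastic matrices
  set.seed(71)
  for (k in 1:20) {
    Q <- random_stochastic()
    a <- sample(0:5, 1); b <- sample(0:5, 1)
    lhs <- unclass(n_step_matrix(Q, a + b))
    rhs <- unclass(n_step_matrix(Q, a)) %*% unclass(n_step_matrix(Q, b))
    expect_lt(max(abs(lhs - rhs)), 1e-10)
    expect_row_stochastic(n_step_matrix(Q, a + b))
  }

  expect_error(n_step_matrix(P, -1), "non-negative")
  expect_error(transition_matrix(matrix(0.5, 5, 5)), "row")
})

test_that("propagation reproduces the observed follow-up shares and conserves mass", {
  P <- fixture_transition_overall()
  shares11 <- c(0.1215, 0.2982, 0.3849, 0.1954)
  out <- propagate(shares11, P)
  expect_lt(abs(out[1] - 0.1296), 0.001)
  expect_equal(sum(out), sum(shares11), tolerance = 1e-12)

  expect_equal(propagate(c(0, 0, 0, 0, 1), P), c(0, 0, 0, 0, 1))
  expect_equal(propagate(c(0.3, 0.3, 0.2, 0.1, 0.1), transition_matrix(diag(5))),
               c(0.3, 0.3, 0.2, 0.1, 0.1))
  expect_error(propagate(1:3, P), "4 or 5 elements")
})

test_that("cohort projection matches the matrix-power oracle and conserves mass", {
  P <- fixture_transition_overall()
  base <- tibble::tibble(year = 2015L, age_group = "all",
                         state = 1:4, count = c(120, 300, 380, 200))
  s <- project_cohorts(base, P, horizon = 2035, annual = FALSE)
  v0 <- c(base$count, 0)
  for (k in 0:10) {
    yr <- 2015 + 2 * k
    got <- dplyr::filter(s, year == yr) |> dplyr::arrange(state)
    oracle <- propagate(v0, n_step_matrix(P, k))
    expect_equal(got$count, oracle, tolerance = 1e-9,
                 label = sprintf("year %d equals base * P^%d", yr, k))
  }
  # mass conservation and death monotonicity
  totals <- dplyr::group_by(s, year) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  expect_true(all(abs(totals$total - sum(base$count)) < 1e-6))
  deaths <- dplyr::filter(s, state == 5) |> dplyr::arrange(year)
  expect_true(all(diff(deaths$count) >= -1e-9))

  # with everyone facing positive death risk, the living mass vanishes
  s_far <- project_cohorts(base, P, horizon = 3615, annual = FALSE)
  final_living <- dplyr::filter(s_far, year == max(year), state != 5)
  expect_lt(sum(final_living$count), 1e-6 * sum(base$count))
  final_dead <- dplyr::filter(s_far, year == max(year), state == 5)
  expect_equal(final_dead$count, sum(base$count), tolerance = 1e-6)
})

test_that("entrants that replace deaths keep the population stationary", {
  d <- 0.1
  K <- cbind(diag(4) * (1 - d), rep(d, 4))
  P <- transition_matrix(rbind(K, c(0, 0, 0, 0, 1)))
  shares <- c(0.1215, 0.2982, 0.3849, 0.1954)
  N <- 1000
  base <- tibble::tibble(year = 2015L, age_group = "all", state = 1:4,
                         count = N * shares)
  ent <- entrants_schedule(2016:2035, rep(d * N / 2, 20),
                           state_shares = shares)
  s <- project_cohorts(base, P, entrants = ent, horizon = 2035,
                       annual = FALSE)
  living <- dplyr::filter(s, state != 5) |>
    dplyr::group_by(year) |> dplyr::summarise(total = sum(count))
  expect_true(all(abs(living$total - N) < 1e-9))
  # and mass accounting includes entrants exactly
  y2035 <- dplyr::filter(s, year == 2035)
  expect_equal(sum(y2035$count), N + d * N * 10, tolerance = 1e-9)
})

test_that("stratified projection ages cohorts forward and pools groups", {
  base <- fixture_populations_2015_by_age()
  mats <- fixture_transition_by_age()
  ent <- read_entrants(eldercast_fixture("entrants_demo.csv"))
  s <- project_cohorts(base, mats, entrants = ent, horizon = 2035)
  expect_s3_class(s, "projection_series")
  expect_setequal(unique(s$age_group), c(age_group_labels(), "all"))
  expect_setequal(unique(s$year), 2015:2035)

  # pooled rows equal the sum over bands every year
  chk <- tibble::as_tibble(s) |>
    dplyr::group_by(year, state) |>
    dplyr::summarise(
      pooled = sum(count[age_group == "all"]),
      parts = sum(count[age_group != "all"]), .groups = "drop")
  expect_equal(chk$pooled, chk$parts, tolerance = 1e-9)

  # grid-year mass accounting: base + entrants = living + cumulative deaths
  g2035 <- dplyr::filter(s, year == 2035, age_group != "all")
  inflow <- sum(ent$entrant_count[ent$year <= 2035])
  expect_equal(sum(g2035$count), sum(base$count) + inflow, tolerance = 1e-6)

  # death monotonicity of the pooled cumulative-death series
  deaths <- dplyr::filter(s, state == 5, age_group == "all") |>
    dplyr::arrange(year)
  expect_true(all(diff(deaths$count) >= -1e-9))

  expect_error(project_cohorts(base, mats["60-64"], horizon = 2035),
               "no transition matrix for age group")
  short <- entrants_schedule(2016:2020, rep(1, 5))
  expect_error(project_cohorts(base, mats, entrants = short, horizon = 2035),
               "no row for year")
  expect_error(project_cohorts(base, mats, horizon = 2010), "after the base")
})

test_that("matrix and series files validate on load and round-trip", {
  m <- read_transition_matrix(eldercast_fixture("transition_60_64.csv"))
  expect_equal(unname(rowSums(unclass(m))), rep(1, 5), tolerance = 1e-12)
  expect_equal(unclass(m)[1, 1], 0.3552, tolerance = 1e-6)
  expect_equal(attr(m, "label"), "60-64")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# label: broken", "# period_years: 2",
               "from_state,s1,s2,s3,s4,s5",
               "1,0.5,0.2,0.15,0.05,0.05", "2,0.2,0.4,0.2,0.1,0.1",
               "3,0.1,0.2,0.4,0.2,0.1", "4,0.05,0.15,0.3,0.3,0.15",
               "5,0,0,0,0,1"), bad)
  expect_error(read_transition_matrix(bad), "row 1 sums to 0.95")

  P <- fixture_transition_overall()
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrix(P, mpath)
  expect_equal(unclass(read_transition_matrix(mpath)), unclass(P),
               tolerance = 1e-12)

  base <- tibble::tibble(year = 2015L, age_group = "all", state = 1:4,
                         count = c(1, 2, 3, 4))
  s <- project_cohorts(base, P, horizon = 2019)
  spath <- withr::local_tempfile(fileext = ".csv")
  write_series(s, spath)
  back <- read_series(spath)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(s),
               ignore_attr = TRUE)
})
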