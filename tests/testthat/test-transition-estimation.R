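test_that("empirical transition matrix matches the counting oracle", {
  # 100 persons from state 1 with destination counts 32/36/23/6/3,
  # plus a handful from each other origin so all rows are estimable
  dests1 <- rep(1:5, times = c(32, 36, 23, 6, 3))
  paired <- tibble::tibble(
    person_id = sprintf("p%03d", seq_len(115)),
    origin = c(rep(1L, 100), rep(2L, 5), rep(3L, 5), rep(4L, 5)),
    dest = c(dests1, rep(2L, 5), rep(3L, 5), rep(4L, 5)),
    age = 70L)
  M <- empirical_transition_matrix(paired)
  expect_row_stochastic(M)
  expect_equal(unname(unclass(M)[1, ]), c(0.32, 0.36, 0.23, 0.06, 0.03))

  # stay-put panel gives the identity on transient states
  stay <- tibble::tibble(person_id = sprintf("s%02d", 1:40),
                         origin = rep(1:4, each = 10),
                         dest = rep(1:4, each = 10), age = 65L)
  expect_equal(unname(unclass(empirical_transition_matrix(stay))), diag(5),
               ignore_attr = TRUE)

  # an unobserved origin is a named estimation error
  expect_error(empirical_transition_matrix(paired[paired$origin != 3, ]),
               "origin state 3")
})

test_that("intercept-only multinomial fit equals the empirical frequency matrix", {
  panel <- make_panel(n = 4000, seed = 21)
  emp <- empirical_transition_matrix(panel)
  fit <- fit_transition_model(panel)
  pred <- predict_transition_matrix(fit)
  expect_row_stochastic(pred)
  expect_lt(max(abs(unclass(pred) - unclass(emp))), 1e-6)
  # optimizer log-likelihood is not below the empirical-frequency value
  paired <- pair_waves(panel)
  K <- unclass(emp)
  ll_emp <- sum(log(K[cbind(paired$origin, paired$dest)]))
  expect_gte(fit$log_likelihood, ll_emp - 1e-6)
})

test_that("large-sample empirical estimate recovers the generating kernel", {
  # aggregate Pearson chi-square over a fixed batch of seeds: under an
  # unbiased generator the total is chi-square with 4 rows x 4 df x 5 seeds
  K <- unclass(overall_kernel())
  x2_total <- 0
  for (s in 1:5) {
    panel <- make_panel(n = 50000, seed = s)
    M <- unclass(empirical_transition_matrix(panel))
    w1 <- dplyr::filter(panel, wave == 1L)
    for (i in 1:4) {
      n_i <- sum(w1$state == i)
      x2_total <- x2_total + n_i * sum((M[i, ] - K[i, ])^2 / K[i, ])
    }
  }
  expect_lt(x2_total, qchisq(0.99, df = 80))
})

test_that("kernel entry bias vanishes at large n over repeated seeds", {
  truth <- truth_from_kernel(overall_kernel())
  K <- unclass(overall_kernel())
  acc <- matrix(0, 5, 5)
  n_rep <- 30
  w1 <- generate_baseline(n = 50000, seed = 23)
  for (r in seq_len(n_rep)) {
    w2 <- simulate_wave2(w1, truth, seed = 4000 + r)
    acc <- acc + unclass(empirical_transition_matrix(
      dplyr::bind_rows(w1, w2)))
  }
  bias <- abs(acc / n_rep - K)
  expect_lt(max(bias[1:4, ]), 0.01)
})

test_that("multinomial coefficients are recovered with near-nominal Wald coverage", {
  truth <- truth_from_kernel(overall_kernel())
  alpha_true <- truth$transition$alpha         # destinations 2..5
  beta_true <- truth$transition$beta           # dest 2..5 x origin 2..4
  hits <- 0L; total <- 0L
  for (r in 1:50) {
    panel <- make_panel(n = 2000, seed = 300 + r, truth = truth)
    fit <- fit_transition_model(panel)
    td <- tidy(fit)
    z99 <- qnorm(0.995)
    for (j in 2:5) {
      rows <- td[td$destination == as.character(j), ]
      truth_vals <- c(`(Intercept)` = alpha_true[j - 1],
                      origin2 = beta_true[j - 1, 1],
                      origin3 = beta_true[j - 1, 2],
                      origin4 = beta_true[j - 1, 3])
      for (term in names(truth_vals)) {
        est <- rows$estimate[rows$term == term]
        se <- rows$std.error[rows$term == term]
        total <- total + 1L
        if (abs(est - truth_vals[[term]]) <= z99 * se) hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("the two parameterizations agree on a large covariate panel", {
  gamma <- matrix(c(0.05, 0.02, -0.02, 0.08), 4, 1,
                  dimnames = list(NULL, "bmi"))
  truth <- truth_from_kernel(overall_kernel())
  truth$transition$gamma <- gamma
  panel <- make_panel(n = 50000, seed = 31, truth = truth)
  fit_m <- fit_transition_model(panel, covariates = "bmi")
  fit_b <- fit_transition_model(panel, covariates = "bmi",
                                parameterization = "binary_renormalized")
  Pm <- predict_transition_matrix(fit_m)
  Pb <- predict_transition_matrix(fit_b)
  expect_row_stochastic(Pm)
  expect_row_stochastic(Pb)
  expect_lt(max(abs(unclass(Pm) - unclass(Pb))), 0.02)

  # profile prediction: rows sum to one, unknown covariate errors
  pr <- predict_transition_matrix(fit_m, profile = list(bmi = 25))
  expect_row_stochastic(pr)
  expect_error(predict_transition_matrix(fit_m, profile = list(bmi = 25,
                                                               shoe = 42)),
               "unknown covariate 'shoe'")
  expect_error(predict_transition_matrix(fit_m, profile = list(female = 1)),
               "lacks covariate 'bmi'")
})

test_that("degenerate inputs are flagged, not silently zeroed", {
  # single origin state: fit works, missing rows are NA with a warning
  paired <- tibble::tibble(person_id = sprintf("q%03d", 1:200),
                           origin = 1L,
                           dest = rep(1:5, each = 40), age = 70L)
  fit <- fit_transition_model(paired)
  expect_warning(m <- predict_transition_matrix(fit), "unobserved")
  expect_true(all(is.na(m[2:4, ])))
  expect_equal(unname(m[5, ]), c(0, 0, 0, 0, 1))
  expect_false(anyNA(m[1, ]))

  panel <- make_panel(n = 500, seed = 33)
  panel$constant_cov <- 1
  expect_error(fit_transition_model(panel, covariates = "constant_cov"),
               "constant")
  expect_error(fit_transition_model(panel, covariates = "no_such_column"),
               "not a panel column")
})

test_that("age stratification is homogeneous under an age-invariant truth", {
  panel <- make_panel(n = 30000, seed = 41)
  overall <- unclass(empirical_transition_matrix(panel))
  mats <- stratified_matrices(panel)
  expect_true(length(mats) >= 4)
  paired <- pair_waves(panel)
  paired$age_group <- age_to_group(paired$age)
  for (lab in names(mats)) {
    expect_row_stochastic(mats[[lab]])
    g <- paired[paired$age_group == lab, ]
    M <- unclass(mats[[lab]])
    for (i in 1:4) {
      n_i <- sum(g$origin == i)
      se <- sqrt(overall[i, ] * (1 - overall[i, ]) / n_i)
      expect_true(all(abs(M[i, ] - overall[i, ]) < 3.5 * se + 1e-12),
                  label = sprintf("%s row %d near overall", lab, i))
    }
  }

  # a sparse band is flagged and excluded
  young <- dplyr::filter(panel, age <= 68)
  mats2 <- stratified_matrices(young)
  expect_true(length(attr(mats2, "flagged")) >= 1)
  expect_false("80+" %in% names(mats2))

  expect_error(age_to_group(70, breaks = c(60, 60, 70)), "strictly increasing")
})

test_that("the published age-specific matrices preserve the printed death gradient", {
  mats <- fixture_transition_by_age()
  expect_equal(sort(names(mats)), sort(age_group_labels()))
  for (m in mats) expect_row_stochastic(m)
  d_young <- unclass(mats[["60-64"]])[4, 5]
  d_old <- unclass(mats[["80+"]])[4, 5]
  expect_gt(d_old, d_young)
  expect_equal(d_young, 0.0349, tolerance = 1e-3)
  expect_equal(d_old, 0.2183, tolerance = 1e-3)
})
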