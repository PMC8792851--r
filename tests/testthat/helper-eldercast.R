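# Shared builders for the test suite. Everything is generated in code;
# seeds are fixed so expectations are stable.

overall_kernel <- function() fixture_transition_overall()

# two-wave panel simulated from an intercept-only truth kernel
make_panel <- function(n, seed, truth = truth_from_kernel(overall_kernel()),
                       spec = covariate_spec(cov_binary("female", 0.5),
                                             cov_continuous("bmi", 23, 3))) {
  w1 <- generate_baseline(spec = spec, n = n, seed = seed)
  w2 <- simulate_wave2(w1, truth)
  dplyr::bind_rows(w1, w2)
}

# truth whose transient kernel is the identity (stay put with prob ~1)
identity_truth <- function() {
  beta <- matrix(-0, 4, 3)
  # destination j gets +60 only when it equals the origin
  beta[1, 1] <- 60  # origin 2 -> dest 2
  beta[2, 2] <- 60  # origin 3 -> dest 3
  beta[3, 3] <- 60  # origin 4 -> dest 4
  generator_truth(
    transition = list(alpha = rep(-30, 4), beta = beta),
    participation = c(`(Intercept)` = 0), level = c(`(Intercept)` = 500),
    residual_sd = 0)
}

# random row-stochastic 5x5 matrix with an absorbing death row
random_stochastic <- function() {
  m <- matrix(stats::rgamma(20, shape = 1) + 1e-3, 4, 5)
  m <- m / rowSums(m)
  transition_matrix(rbind(m, c(0, 0, 0, 0, 1)))
}

# per-row Pearson chi-square goodness-of-fit of an estimated kernel row
# against the generating row (simultaneous 5-cell check at level alpha)
expect_kernel_recovered <- function(M, K, n_by_origin, alpha = 0.01) {
  for (i in 1:4) {
    x2 <- n_by_origin[i] * sum((M[i, ] - K[i, ])^2 / K[i, ])
    expect_lt(x2, stats::qchisq(1 - alpha, df = 4),
              label = sprintf("chi-square of kernel row %d", i))
  }
}

expect_row_stochastic <- function(P, tol = 1e-9) {
  m <- unclass(P)
  expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
  expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = tol)
  expect_equal(unname(m[5, ]), c(0, 0, 0, 0, 1), tolerance = 1e-12)
}
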