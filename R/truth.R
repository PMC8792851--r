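#' Ground-truth parameters for the synthetic panel generator
#'
#' The generator draws wave-2 states from a multinomial-logit transition
#' kernel and expenditures from a probit-participation plus linear-level
#' process, so every estimation stage can be validated against known
#' parameters.
#'
#' The transition component is parameterized per destination state
#' `j in 2..5` relative to the reference destination 1: a linear predictor
#' `alpha_j + beta_j[origin] + gamma_j . x` where `beta_j` holds offsets
#' for origin states 2-4 (origin 1 is the reference) and `gamma_j` are
#' covariate slopes. The expenditure component uses named coefficient
#' vectors over design columns (`"(Intercept)"`, `"state"`, covariate
#' names): care is sought when `x . delta1 + N(0,1) >= 0`, and positive
#' expenditure is `max(x . delta2 + N(0, sigma), 0)`.
#'
#' @param transition List with `alpha` (length-4 vector, destinations
#'   2..5), `beta` (4 x 3 matrix, destinations 2..5 by origins 2..4) and
#'   optional `gamma` (4 x k matrix with column names matching covariates).
#' @param participation Named numeric vector `delta1`.
#' @param level Named numeric vector `delta2`.
#' @param residual_sd Residual standard deviation `sigma` of the level
#'   part, in yuan; must be `>= 0`.
#' @param period_years Panel wave spacing in years.
#' @return A `generator_truth` object.
#' @examples
#' tr <- truth_from_kernel(fixture_transition_overall())
#' tr$transition$alpha
#' @export
generator_truth <- function(transition, participation, level, residual_sd,
                            period_years = 2) {
  if (residual_sd < 0) abort("residual_sd must be >= 0")
  if (!is.list(transition) || is.null(transition$alpha) || is.null(transition$beta)) {
    abort("transition must be a list with elements alpha and beta")
  }
  if (length(transition$alpha) != 4) abort("transition$alpha must have length 4")
  beta <- as.matrix(transition$beta)
  if (!all(dim(beta) == c(4, 3))) {
    abort("transition$beta must be 4 x 3 (destinations 2..5 by origins 2..4)")
  }
  gamma <- transition$gamma
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    if (nrow(gamma) != 4 || is.null(colnames(gamma))) {
      abort("transition$gamma must have 4 rows and named columns")
    }
  }
  if (is.null(names(participation)) || is.null(names(level))) {
    abort("participation and level coefficient vectors must be named")
  }
  structure(
    list(transition = list(alpha = as.numeric(transition$alpha), beta = beta,
                           gamma = gamma),
         participation = participation, level = level,
         residual_sd = residual_sd, period_years = period_years),
    class = "generator_truth")
}

#' Intercept-only generator truth reproducing a given kernel
#'
#' Inverts the multinomial-logit parameterization so that, with all
#' covariate slopes zero, the implied transition kernel equals `P` on the
#' transient rows. Requires strictly positive probabilities in rows 1-4.
#'
#' @param P A [transition_matrix()] with positive transient-row entries.
#' @param participation,level,residual_sd Expenditure components passed on
#'   to [generator_truth()]; defaults give a participation probability
#'   rising with worse health and a level equation linear in the state.
#' @return A `generator_truth` whose kernel equals `P`.
#' @export
truth_from_kernel <- function(P,
                              participation = c(`(Intercept)` = -0.608,
                                                state = 0.261),
                              level = c(`(Intercept)` = 0, state = 160),
                              residual_sd = 120) {
  if (!is_transition_matrix(P)) P <- transition_matrix(P)
  m <- unclass(P)
  if (any(m[1:4, ] <= 0)) {
    abort("truth_from_kernel needs strictly positive transient-row entries")
  }
  lo <- log(m[1:4, 2:5] / m[1:4, 1])    # origins 1..4 x destinations 2..5
  alpha <- lo[1, ]
  beta <- t(lo[2:4, , drop = FALSE]) - alpha  # dest 2..5 x origin 2..4
  generator_truth(
    transition = list(alpha = alpha, beta = beta, gamma = NULL),
    participation = participation, level = level, residual_sd = residual_sd,
    period_years = attr(P, "period_years") %||% 2)
}

#' Transition kernel implied by a generator truth
#'
#' @param truth A [generator_truth()].
#' @param covariates Optional single-row data frame (or named list) of
#'   covariate values at which to evaluate `gamma` terms; ignored when the
#'   truth has no covariate slopes.
#' @return A [transition_matrix()].
#' @export
kernel_from_truth <- function(truth, covariates = NULL) {
  stopifnot(inherits(truth, "generator_truth"))
  shift <- rep(0, 4)
  gamma <- truth$transition$gamma
  if (!is.null(gamma)) {
    if (is.null(covariates)) abort("truth has covariate slopes; supply covariates")
    x <- unlist(covariates[colnames(gamma)])
    shift <- as.numeric(gamma %*% x)
  }
  rows <- t(vapply(1:4, function(i) {
    eta <- truth$transition$alpha + shift
    if (i > 1) eta <- eta + truth$transition$beta[, i - 1]
    p <- c(1, exp(eta))
    p / sum(p)
  }, numeric(5)))
  transition_matrix(rbind(rows, c(0, 0, 0, 0, 1)),
                    period_years = truth$period_years)
}

# Linear predictor of a named coefficient vector over panel columns.
# "(Intercept)" maps to 1; every other name must be a column of `data`.
truth_linpred <- function(coefs, data) {
  terms <- names(coefs)
  eta <- rep(0, nrow(data))
  for (k in seq_along(coefs)) {
    if (terms[k] == "(Intercept)") {
      eta <- eta + coefs[k]
    } else {
      if (!terms[k] %in% names(data)) {
        abort(sprintf("coefficient '%s' has no matching panel column", terms[k]))
      }
      v <- data[[terms[k]]]
      if (!is.numeric(v)) abort(sprintf("column '%s' must be numeric", terms[k]))
      eta <- eta + coefs[k] * v
    }
  }
  eta
}
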