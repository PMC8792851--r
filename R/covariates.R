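#' Covariate specifications for the synthetic panel generator
#'
#' A covariate spec describes one baseline covariate and how to draw it:
#' binary (Bernoulli), categorical (multinomial over named levels), or
#' continuous (normal). `covariate_spec()` bundles several into a
#' validated list. `default_covariate_spec()` mirrors the variable list of
#' the CHARLS-style analysis the generator emulates: demographics (gender,
#' household registration), socioeconomic status (education, family
#' income, pension, medical insurance), health behaviours (chronic
#' disease, drinking, smoking, BMI) and social relations (marital status,
#' social activities). The default distributions are generator
#' conventions, not estimates of any survey's composition.
#'
#' @param name Covariate name (must be a valid column name).
#' @param p Bernoulli success probability for binary covariates.
#' @param levels,probs Category labels and probabilities (summing to 1).
#' @param mean,sd Normal parameters for continuous covariates (`sd > 0`).
#' @param reference_level Optional reference category label.
#' @param ... `cov_*()` objects passed to `covariate_spec()`.
#' @return `cov_binary()`, `cov_categorical()` and `cov_continuous()`
#'   return single covariate definitions; `covariate_spec()` returns a
#'   named `covariate_spec` list.
#' @examples
#' covariate_spec(cov_binary("female", 0.5), cov_continuous("bmi", 23, 3))
#' @name covariate-spec
NULL

#' @rdname covariate-spec
#' @export
cov_binary <- function(name, p = 0.5) {
  if (p < 0 || p > 1) abort(sprintf("p for '%s' must be in [0, 1]", name))
  structure(list(name = name, kind = "binary", p = p), class = "eldercast_cov")
}

#' @rdname covariate-spec
#' @export
cov_categorical <- function(name, levels, probs, reference_level = levels[1]) {
  if (length(levels) != length(probs)) {
    abort(sprintf("'%s': levels and probs differ in length", name))
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    abort(sprintf("'%s': category probabilities must be >= 0 and sum to 1", name))
  }
  if (!reference_level %in% levels) {
    abort(sprintf("'%s': reference level not among levels", name))
  }
  structure(list(name = name, kind = "categorical", levels = levels,
                 probs = probs, reference_level = reference_level),
            class = "eldercast_cov")
}

#' @rdname covariate-spec
#' @export
cov_continuous <- function(name, mean = 0, sd = 1) {
  if (sd <= 0) abort(sprintf("'%s': sd must be > 0", name))
  structure(list(name = name, kind = "continuous", mean = mean, sd = sd),
            class = "eldercast_cov")
}

#' @rdname covariate-spec
#' @export
covariate_spec <- function(...) {
  covs <- list(...)
  if (length(covs) == 1 && is.list(covs[[1]]) &&
      !inherits(covs[[1]], "eldercast_cov")) {
    covs <- covs[[1]]
  }
  if (length(covs) == 0) abort("covariate spec must contain at least one covariate")
  ok <- vapply(covs, inherits, logical(1), "eldercast_cov")
  if (!all(ok)) abort("all elements must be cov_binary/cov_categorical/cov_continuous")
  nms <- vapply(covs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("duplicate covariate names in spec")
  structure(setNames(covs, nms), class = "covariate_spec")
}

#' @rdname covariate-spec
#' @export
default_covariate_spec <- function() {
  covariate_spec(
    cov_binary("female", 0.5),
    cov_binary("agricultural_hukou", 0.6),
    cov_binary("middle_school_or_above", 0.35),
    cov_continuous("log_family_income", mean = 9.5, sd = 1.1),
    cov_binary("pension", 0.45),
    cov_binary("medical_insurance", 0.9),
    cov_binary("has_spouse", 0.75),
    cov_binary("social_activities", 0.45),
    cov_binary("chronic_disease", 0.6),
    cov_binary("drinking", 0.3),
    cov_binary("smoking", 0.3),
    cov_continuous("bmi", mean = 23, sd = 3)
  )
}

# Draw n rows of covariates. Binary covariates come back as 0/1 doubles and
# categorical ones as character so a written panel round-trips losslessly
# through CSV type guessing.
sample_covariates <- function(spec, n) {
  if (!inherits(spec, "covariate_spec")) spec <- covariate_spec(spec)
  cols <- lapply(spec, function(cv) {
    switch(cv$kind,
      binary = as.double(rbinom(n, 1, cv$p)),
      categorical = sample(cv$levels, n, replace = TRUE, prob = cv$probs),
      continuous = rnorm(n, cv$mean, cv$sd)
    )
  })
  tibble::as_tibble(cols)
}
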