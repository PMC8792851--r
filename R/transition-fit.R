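#' Pair the two waves of a panel into transition records
#'
#' Matches wave-1 and wave-2 rows by `person_id` and returns one row per
#' individual with the origin state, destination state, and the wave-1
#' age and covariates.
#'
#' @param panel Long panel tibble with waves 1 and 2.
#' @return Tibble with `person_id`, `origin`, `dest`, `age` and the
#'   covariate columns (wave-1 values).
#' @export
pair_waves <- function(panel) {
  w1 <- dplyr::filter(panel, .data$wave == 1L)
  w2 <- dplyr::filter(panel, .data$wave == 2L)
  if (anyDuplicated(w1$person_id) || anyDuplicated(w2$person_id)) {
    abort("duplicate person_id within a wave")
  }
  keep <- setdiff(names(w1), c("wave", "sought_care",
                               "family_annual_expenditure",
                               "individual_monthly_expenditure"))
  paired <- dplyr::inner_join(
    dplyr::select(w1, dplyr::all_of(keep)) |> dplyr::rename(origin = "state"),
    dplyr::select(w2, "person_id", dest = "state"),
    by = "person_id")
  if (nrow(paired) == 0) abort("no matched wave-1/wave-2 pairs in panel")
  paired
}

#' Empirical transition frequency matrix
#'
#' The nonparametric oracle for the model-based estimates: entry (i, j) is
#' the observed fraction of individuals in state i at wave 1 who are in
#' state j at wave 2. Every transient origin state must be observed.
#'
#' @param panel Long panel tibble (waves 1 and 2), or a paired tibble from
#'   [pair_waves()].
#' @param label Label stored on the result.
#' @return A [transition_matrix()].
#' @export
empirical_transition_matrix <- function(panel, label = "overall") {
  paired <- if (all(c("origin", "dest") %in% names(panel))) panel
            else pair_waves(panel)
  paired <- dplyr::filter(paired, .data$origin %in% transient_states())
  missing_origin <- setdiff(transient_states(), unique(paired$origin))
  if (length(missing_origin) > 0) {
    abort(sprintf("no observations with origin state %d", missing_origin[1]))
  }
  counts <- table(factor(paired$origin, levels = 1:4),
                  factor(paired$dest, levels = 1:5))
  m <- rbind(unclass(counts) / rowSums(counts), c(0, 0, 0, 0, 1))
  transition_matrix(m, label = label, renormalize = TRUE)
}

#' Fit the covariate transition model
#'
#' Models the destination-state distribution of each individual given
#' their origin state (four indicator variables, origin 1 reference) and
#' covariates. The canonical parameterization is a multinomial logit over
#' destinations (reference destination 1), whose predicted rows are
#' stochastic by construction. The `binary_renormalized` compatibility
#' mode instead fits one binary logit per destination and renormalizes
#' each predicted row; it mirrors a per-destination odds formulation that
#' does not itself guarantee unit row sums.
#'
#' @param panel Long panel tibble or paired tibble ([pair_waves()]).
#' @param covariates Character vector of covariate column names (possibly
#'   empty for an intercept + origin model).
#' @param parameterization `"multinomial"` or `"binary_renormalized"`.
#' @return A `transition_model_fit` object.
#' @examples
#' p1 <- generate_baseline(n = 400, seed = 7)
#' p2 <- simulate_wave2(p1, truth_from_kernel(fixture_transition_overall()))
#' fit <- fit_transition_model(dplyr::bind_rows(p1, p2))
#' predict_transition_matrix(fit)
#' @export
fit_transition_model <- function(panel, covariates = character(),
                                 parameterization = c("multinomial",
                                                      "binary_renormalized")) {
  parameterization <- match.arg(parameterization)
  paired <- if (all(c("origin", "dest") %in% names(panel))) panel
            else pair_waves(panel)
  paired <- dplyr::filter(paired, .data$origin %in% transient_states())
  for (cv in covariates) {
    if (!cv %in% names(paired)) {
      abort(sprintf("covariate '%s' is not a panel column", cv))
    }
    if (dplyr::n_distinct(paired[[cv]]) < 2) {
      abort(sprintf("covariate '%s' is constant", cv))
    }
  }
  origins_observed <- sort(unique(paired$origin))
  dat <- paired
  dat$origin <- factor(dat$origin, levels = origins_observed)
  dat$dest <- factor(dat$dest, levels = 1:5)
  rhs <- paste(c("origin", covariates), collapse = " + ")
  if (length(origins_observed) == 1) rhs <- paste(c("1", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("dest ~", rhs))
  mm <- stats::model.matrix(fml, dat)
  if (qr(mm)$rank < ncol(mm)) abort("singular design matrix")
  if (parameterization == "multinomial") {
    model <- nnet::multinom(fml, data = dat, trace = FALSE,
                            maxit = 500, reltol = 1e-13)
    ll <- as.numeric(stats::logLik(model))
  } else {
    model <- lapply(1:5, function(j) {
      yj <- as.integer(dat$dest == j)
      glm(stats::as.formula(paste("yj ~", rhs)),
          data = dplyr::mutate(dat, yj = yj), family = binomial("logit"))
    })
    pr <- vapply(model, predict, numeric(nrow(dat)), type = "response")
    pr <- pr / rowSums(pr)
    ll <- sum(log(pr[cbind(seq_len(nrow(dat)), as.integer(dat$dest))]))
  }
  structure(
    list(model = model, parameterization = parameterization,
         covariate_names = covariates, data = dat,
         origins_observed = origins_observed,
         n_used = nrow(dat), log_likelihood = ll),
    class = "transition_model_fit")
}

#' @export
print.transition_model_fit <- function(x, ...) {
  cat(sprintf("<transition_model_fit> %s, n = %d, logLik = %.2f\n",
              x$parameterization, x$n_used, x$log_likelihood))
  cat(sprintf("covariates: %s\n",
              if (length(x$covariate_names)) paste(x$covariate_names,
                                                   collapse = ", ")
              else "(origin indicators only)"))
  invisible(x)
}

predict_dest_probs <- function(fit, newdata) {
  if (fit$parameterization == "multinomial") {
    pr <- predict(fit$model, newdata = newdata, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
  } else {
    pr <- vapply(fit$model, predict, numeric(nrow(newdata)),
                 newdata = newdata, type = "response")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    pr <- pr / rowSums(pr)
  }
  pr
}

#' Predict a transition matrix from a fitted transition model
#'
#' Row i is the predicted destination distribution from origin state i.
#' With `profile = "sample-average"` the prediction is marginalized by
#' averaging predicted probabilities over the fitting sample's covariate
#' rows (a population-averaged matrix), not by predicting at average
#' covariates. A named profile predicts at one covariate setting.
#'
#' @param fit A `transition_model_fit`.
#' @param profile `"sample-average"` or a named list / one-row data frame
#'   covering all fitted covariates.
#' @param label Label for the resulting matrix.
#' @return A [transition_matrix()]. If some transient origin state was
#'   unobserved at fitting, its row cannot be predicted: the function
#'   warns and returns a plain matrix with `NA` in those rows instead.
#' @export
predict_transition_matrix <- function(fit, profile = "sample-average",
                                      label = "overall") {
  stopifnot(inherits(fit, "transition_model_fit"))
  if (identical(profile, "sample-average")) {
    base <- fit$data
  } else {
    profile <- tibble::as_tibble(as.list(profile))
    unknown <- setdiff(names(profile), names(fit$data))
    if (length(unknown) > 0) {
      abort(sprintf("unknown covariate '%s' in profile", unknown[1]))
    }
    missing_cov <- setdiff(fit$covariate_names, names(profile))
    if (length(missing_cov) > 0) {
      abort(sprintf("profile lacks covariate '%s'", missing_cov[1]))
    }
    base <- profile
  }
  rows <- matrix(NA_real_, 4, 5)
  for (i in transient_states()) {
    if (!i %in% fit$origins_observed) next
    nd <- base
    nd$origin <- factor(i, levels = fit$origins_observed)
    rows[i, ] <- colMeans(predict_dest_probs(fit, nd))
  }
  m <- rbind(rows, c(0, 0, 0, 0, 1))
  if (anyNA(rows)) {
    warning("origin states ",
            paste(setdiff(transient_states(), fit$origins_observed),
                  collapse = ", "),
            " were unobserved at fitting; their rows are NA", call. = FALSE)
    dimnames(m) <- list(from = as.character(1:5), to = as.character(1:5))
    return(m)
  }
  transition_matrix(m, label = label, renormalize = TRUE, tol = 1e-6)
}

#' Age-stratified transition matrices
#'
#' Splits the matched pairs by wave-1 age band and estimates one
#' empirical transition matrix per band. Bands with fewer than `min_n`
#' pairs, or missing some origin state, are flagged and excluded (their
#' labels are returned in the `"flagged"` attribute).
#'
#' @param panel Long panel tibble or paired tibble.
#' @param age_breaks Strictly increasing lower bounds of the age bands.
#' @param min_n Minimum matched pairs per band.
#' @return Named list of [transition_matrix()] objects with attribute
#'   `flagged` (character vector of excluded band labels).
#' @export
stratified_matrices <- function(panel, age_breaks = c(60, 65, 70, 75, 80),
                                min_n = 30) {
  paired <- if (all(c("origin", "dest") %in% names(panel))) panel
            else pair_waves(panel)
  paired$age_group <- age_to_group(paired$age, age_breaks)
  groups <- split(paired, paired$age_group)
  out <- list()
  flagged <- character()
  for (lab in names(groups)) {
    g <- groups[[lab]]
    if (nrow(g) < min_n ||
        length(setdiff(transient_states(), unique(g$origin))) > 0) {
      flagged <- c(flagged, lab)
      next
    }
    out[[lab]] <- empirical_transition_matrix(g, label = lab)
  }
  attr(out, "flagged") <- flagged
  out
}

#' Tidy coefficients of a transition model fit
#'
#' @param x A `transition_model_fit`.
#' @param ... Unused.
#' @return Tibble with `destination`, `term`, `estimate`, `std.error`.
#' @export
tidy.transition_model_fit <- function(x, ...) {
  if (x$parameterization == "multinomial") {
    co <- coef(x$model)
    se <- summary(x$model)$standard.errors
    if (is.null(dim(co))) {  # only two destination levels observed
      co <- matrix(co, nrow = 1, dimnames = list("2", names(co)))
      se <- matrix(se, nrow = 1, dimnames = list("2", colnames(co)))
    }
    tibble::tibble(
      destination = rep(rownames(co), times = ncol(co)),
      term = rep(colnames(co), each = nrow(co)),
      estimate = as.vector(co),
      std.error = as.vector(se))
  } else {
    purrr::map_dfr(seq_along(x$model), function(j) {
      s <- summary(x$model[[j]])$coefficients
      tibble::tibble(destination = as.character(j), term = rownames(s),
                     estimate = s[, 1], std.error = s[, 2])
    })
  }
}

#' @export
glance.transition_model_fit <- function(x, ...) {
  tibble::tibble(parameterization = x$parameterization, n = x$n_used,
                 logLik = x$log_likelihood,
                 n_covariates = length(x$covariate_names))
}
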