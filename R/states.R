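#' Health state coding
#'
#' The package works on a five-state discrete health scale built from
#' self-rated health survey items: 1 = healthy, 2 = basically healthy,
#' 3 = unhealthy, 4 = very unhealthy, 5 = death. States 1-4 are transient;
#' state 5 is absorbing.
#'
#' @format `health_states()` returns the integer vector `1:5`;
#'   `transient_states()` returns `1:4`; `death_state()` returns `5L`.
#' @name health-states
NULL

#' @rdname health-states
#' @export
health_states <- function() 1:5

#' @rdname health-states
#' @export
transient_states <- function() 1:4

#' @rdname health-states
#' @export
death_state <- function() 5L

#' @rdname health-states
#' @export
state_labels <- function() {
  c(`1` = "healthy", `2` = "basically healthy", `3` = "unhealthy",
    `4` = "very unhealthy", `5` = "death")
}

#' Default five-year age bands for stratified estimation
#'
#' @return Character vector of band labels: `"60-64"`, `"65-69"`, `"70-74"`,
#'   `"75-79"`, `"80+"`.
#' @export
age_group_labels <- function() c("60-64", "65-69", "70-74", "75-79", "80+")

#' Assign ages to five-year age bands
#'
#' @param age Integer vector of ages in years (>= 60).
#' @param breaks Lower bounds of the bands; the last band is open-ended.
#' @return Factor with levels formed from `breaks`.
#' @examples
#' age_to_group(c(60, 64, 71, 83))
#' @export
age_to_group <- function(age, breaks = c(60, 65, 70, 75, 80)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing.")
  }
  if (any(age < breaks[1], na.rm = TRUE)) {
    abort(sprintf("ages below %d are outside the modelled population", breaks[1]))
  }
  nb <- length(breaks)
  labels <- c(paste0(breaks[-nb], "-", breaks[-1] - 1), paste0(breaks[nb], "+"))
  cut(age, breaks = c(breaks, Inf), labels = labels, right = FALSE)
}

check_states <- function(state, allow_death = TRUE) {
  ok <- health_states()
  if (!allow_death) ok <- transient_states()
  bad <- which(!(state %in% ok))
  if (length(bad) > 0) {
    abort(sprintf("invalid health state code %s at position %d",
                  format(state[bad[1]]), bad[1]))
  }
  invisible(as.integer(state))
}
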