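#' Construct a health-state transition probability matrix
#'
#' A `transition_matrix` is a 5 x 5 row-stochastic matrix over the health
#' states, describing one estimation period (two years by default). Row 5
#' is the absorbing death row `(0, 0, 0, 0, 1)` exactly.
#'
#' @param x Numeric 5 x 5 matrix (rows = origin states, columns =
#'   destination states) or an object coercible to one.
#' @param label Character label, `"overall"` or an age band such as
#'   `"60-64"`.
#' @param period_years Length of the transition period in years.
#' @param renormalize If `TRUE`, rows whose sums deviate from 1 by at most
#'   `tol` are rescaled to sum exactly to 1 (published matrices rounded to
#'   4 decimals can be off by a few 1e-4, which matrix powers would
#'   amplify). Rows outside `tol` are an error either way.
#' @param tol Maximum tolerated absolute row-sum deviation at validation.
#' @return A `transition_matrix` object.
#' @examples
#' P <- transition_matrix(diag(5))
#' n_step_matrix(P, 3)
#' @export
transition_matrix <- function(x, label = "overall", period_years = 2,
                              renormalize = FALSE, tol = 5e-4) {
  m <- as.matrix(x)
  if (!is.numeric(m) || !all(dim(m) == c(5L, 5L))) {
    abort("a transition matrix must be a numeric 5 x 5 matrix")
  }
  if (any(!is.finite(m))) abort("transition probabilities must be finite")
  if (any(m < -1e-12 | m > 1 + 1e-12)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  m[m < 0] <- 0
  m[m > 1] <- 1
  rs <- rowSums(m)
  dev <- abs(rs - 1)
  if (any(dev > tol)) {
    bad <- which.max(dev)
    abort(sprintf("row %d sums to %.4f, outside tolerance %.1e of 1",
                  bad, rs[bad], tol))
  }
  if (renormalize) {
    m <- m / rs
  } else if (any(dev > 1e-9)) {
    bad <- which(dev > 1e-9)[1]
    abort(sprintf(
      "row %d sums to %.6f; pass renormalize = TRUE to rescale rounded rows",
      bad, rs[bad]))
  }
  if (!isTRUE(all.equal(unname(m[5, ]), c(0, 0, 0, 0, 1), tolerance = 1e-9))) {
    abort("row 5 must be the absorbing death row (0, 0, 0, 0, 1)")
  }
  m[5, ] <- c(0, 0, 0, 0, 1)
  dimnames(m) <- list(from = as.character(1:5), to = as.character(1:5))
  structure(m, label = label, period_years = period_years,
            class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<transition_matrix> label = %s, period = %s years\n",
              attr(x, "label"), attr(x, "period_years")))
  m <- round(unclass(x), digits)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  print(m, ...)
  invisible(x)
}

is_transition_matrix <- function(x) inherits(x, "transition_matrix")

#' n-step transition matrix by Chapman-Kolmogorov composition
#'
#' Computes the matrix power `P^n`, the n-step transition kernel of the
#' discrete-time chain. `n = 0` gives the identity.
#'
#' @param P A [transition_matrix()].
#' @param n Non-negative integer number of steps.
#' @return A `transition_matrix` spanning `n * period_years` years.
#' @export
n_step_matrix <- function(P, n) {
  if (!is_transition_matrix(P)) P <- transition_matrix(P)
  if (length(n) != 1 || n < 0 || n != round(n)) {
    abort("`n` must be a single non-negative integer")
  }
  out <- diag(5)
  base <- unclass(P)
  k <- as.integer(n)
  # exponentiation by squaring; powers stay row-stochastic up to roundoff
  while (k > 0) {
    if (k %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    k <- k %/% 2L
  }
  out <- out / rowSums(out)
  out[5, ] <- c(0, 0, 0, 0, 1)
  transition_matrix(out, label = attr(P, "label"),
                    period_years = attr(P, "period_years") * n)
}

#' Propagate a state distribution one step through a transition matrix
#'
#' Left-multiplies a distribution (shares or person counts) over the five
#' states by the kernel: `out = dist %*% P`. Total mass (living plus dead)
#' is conserved.
#'
#' @param dist Numeric vector of length 5 (states 1-5), shares or counts;
#'   a length-4 vector over the transient states is padded with a zero
#'   death entry.
#' @param P A [transition_matrix()].
#' @return Numeric length-5 vector of the same total mass.
#' @examples
#' P <- read_transition_matrix(eldercast_fixture("transition_overall.csv"))
#' propagate(c(0.1215, 0.2982, 0.3849, 0.1954), P)
#' @export
propagate <- function(dist, P) {
  if (!is_transition_matrix(P)) P <- transition_matrix(P)
  if (length(dist) == 4) dist <- c(dist, 0)
  if (length(dist) != 5) abort("`dist` must have 4 or 5 elements")
  if (any(dist < 0) || any(!is.finite(dist))) {
    abort("`dist` must be non-negative and finite")
  }
  as.numeric(dist %*% unclass(P))
}

#' Read and write transition matrix CSV files
#'
#' The on-disk format is a CSV with two leading comment lines
#' (`# label: ...`, `# period_years: ...`), a header row, and five rows of
#' `from_state, s1..s5`. Row sums are validated at load; rows off by at
#' most `tol` (rounding of published 4-decimal tables) are rescaled to sum
#' exactly to one.
#'
#' @param path File path.
#' @param tol Row-sum tolerance applied at load.
#' @return `read_transition_matrix()` returns a [transition_matrix()];
#'   `write_transition_matrix()` returns `path` invisibly.
#' @export
read_transition_matrix <- function(path, tol = 5e-4) {
  header <- readLines(path, n = 10)
  meta <- grep("^#", header, value = TRUE)
  pick <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  label <- pick("label", "overall")
  period <- as.numeric(pick("period_years", "2"))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!identical(names(df)[1], "from_state") || nrow(df) != 5) {
    abort(sprintf("'%s' is not a 5-state transition matrix CSV", path))
  }
  m <- as.matrix(df[order(df$from_state), -1, drop = FALSE])
  transition_matrix(m, label = label, period_years = period,
                    renormalize = TRUE, tol = tol)
}

#' @rdname read_transition_matrix
#' @param P A [transition_matrix()] to serialize.
#' @param digits Decimal places written; `NA` writes full precision.
#' @export
write_transition_matrix <- function(P, path, digits = NA) {
  if (!is_transition_matrix(P)) P <- transition_matrix(P)
  m <- unclass(P)
  if (!is.na(digits)) m <- round(m, digits)
  lines <- c(
    sprintf("# label: %s", attr(P, "label")),
    sprintf("# period_years: %s", attr(P, "period_years")),
    "from_state,s1,s2,s3,s4,s5",
    vapply(1:5, function(i) {
      paste(c(i, format(m[i, ], trim = TRUE, scientific = FALSE)),
            collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a directory or set of transition matrix files
#'
#' @param paths Character vector of CSV files, or a single directory whose
#'   `*.csv` files are all read.
#' @param tol Row-sum tolerance passed to [read_transition_matrix()].
#' @return Named list of [transition_matrix()] objects, keyed by label.
#' @export
read_matrices <- function(paths, tol = 5e-4) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  }
  mats <- lapply(paths, read_transition_matrix, tol = tol)
  setNames(mats, vapply(mats, attr, character(1), "label"))
}

#' Tidy a transition matrix into long format
#'
#' @param x A [transition_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `probability`, `label`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    from = rep(1:5, times = 5),
    to = rep(1:5, each = 5),
    probability = as.vector(m),
    label = attr(x, "label")
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' Heatmap of a transition matrix
#'
#' @param object A [transition_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$to), y = factor(.data$from),
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$probability)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(as.character(1:5))) +
    ggplot2::labs(x = "destination state", y = "origin state",
                  title = sprintf("Transition probabilities (%s)",
                                  attr(object, "label"))) +
    ggplot2::theme_minimal()
}
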