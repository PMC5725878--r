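#' Simulate an applicant pool
#'
#' Draws `n_applicants` rows of `(x1, x2, y)` from the trivariate standard
#' normal with the spec's correlation matrix.  By default this is an ordinary
#' random draw, so realized sample correlations scatter around the population
#' values (as they would in a real cohort); `exact_moments = TRUE` rescales
#' the draw so the sample moments match the spec exactly (useful for
#' debugging).  The outcome is present for every row at this stage; apply
#' [apply_selection()] to mask it for rejected applicants.
#'
#' @param spec a [correlation_spec()].
#' @param seed integer seed for reproducibility, or `NULL` to use the current
#'   RNG state.
#' @param exact_moments logical; match sample moments exactly.
#' @return a tibble with columns `x1`, `x2`, `y`.
#' @examples
#' simulate_applicants(correlation_spec(.6, .2, 0, 100), seed = 42)
#' @export
simulate_applicants <- function(spec, seed = NULL, exact_moments = FALSE) {
  if (!inherits(spec, "correlation_spec")) {
    abort_config("`spec` must be a correlation_spec.")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- MASS::mvrnorm(
    n = spec$n_applicants, mu = c(0, 0, 0), Sigma = spec$corr,
    empirical = exact_moments
  )
  tibble(x1 = X[, 1], x2 = X[, 2], y = X[, 3])
}

#' Apply compensatory top-fraction selection
#'
#' Computes the composite `z`, admits the `ceiling(rate * n)` applicants with
#' the highest `z` (ties broken by stable input order), and masks the outcome
#' of every rejected applicant — after selection, `y` is observed iff
#' `selected`.  `x1`, `x2` and `z` are never altered.
#'
#' @param data an applicant table with complete `x1`, `x2`.
#' @param design a [selection_design()].
#' @return a tibble with columns `x1, x2, z, selected, y`.
#' @examples
#' pool <- simulate_applicants(correlation_spec(.6, .2, 0, 100), seed = 1)
#' apply_selection(pool, selection_design(1, 1, 0.2))
#' @export
apply_selection <- function(data, design) {
  if (!inherits(design, "selection_design")) {
    abort_config("`design` must be a selection_design.")
  }
  data <- as_applicant_table(data)
  z <- design$weight_x1 * data$x1 + design$weight_x2 * data$x2
  k <- ceiling(design$selection_rate * nrow(data))
  sel <- rank(-z, ties.method = "first") <= k
  tibble(
    x1 = data$x1, x2 = data$x2, z = z, selected = sel,
    y = ifelse(sel, data$y, NA_real_)
  )
}

#' Closed-form moments of an upper-truncated standard normal
#'
#' For selection of the top `rate` fraction on a standard normal variable,
#' with cutpoint `c = qnorm(1 - rate)` and hazard
#' `lambda = dnorm(c) / rate`: the truncated mean is `lambda` and the
#' truncated/untruncated variance ratio is `1 - lambda * (lambda - c)`.
#' These are the analytic anchors used to validate the simulator's
#' selection geometry.
#'
#' @param selection_rate fraction selected, in `(0, 1]`.
#' @return a one-row tibble with `cutpoint`, `hazard`, `mean_shift`,
#'   `variance_ratio`.
#' @examples
#' truncation_moments(0.2)
#' @export
truncation_moments <- function(selection_rate) {
  check_number(selection_rate, "selection_rate", 0, 1, allow_min = FALSE)
  if (selection_rate == 1) {
    return(tibble(
      cutpoint = -Inf, hazard = 0, mean_shift = 0, variance_ratio = 1
    ))
  }
  c0 <- qnorm(1 - selection_rate)
  lambda <- dnorm(c0) / selection_rate
  tibble(
    cutpoint = c0,
    hazard = lambda,
    mean_shift = lambda,
    variance_ratio = 1 - lambda * (lambda - c0)
  )
}

#' Scatterplot of the two predictors, colored by admission
#'
#' Visualizes the compensatory-selection geometry: the admitted group lies
#' above a diagonal boundary in the `(x1, x2)` plane, which induces a
#' negative predictor intercorrelation among incumbents.
#'
#' @param data an applicant table with a `selected` column.
#' @return a ggplot object.
#' @export
plot_selection <- function(data) {
  data <- as_applicant_table(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$x1, .data$x2,
    color = ifelse(.data$selected, "incumbent", "rejected")
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(color = NULL, x = "x1 (test)", y = "x2") +
    ggplot2::theme_minimal()
}
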