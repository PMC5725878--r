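#' Specify the applicant-pool correlation structure
#'
#' The applicant pool is modelled as a trivariate standard normal
#' (predictor `x1`, second predictor `x2`, outcome `y`) with the given
#' pairwise correlations.  The implied correlation matrix must be positive
#' semidefinite and the pool must contain at least 3 applicants.
#'
#' @param rho_yx1 population correlation between outcome and the predictor of
#'   interest, in `[-1, 1]`.
#' @param rho_yx2 population correlation between outcome and the second
#'   predictor.
#' @param rho_x1x2 population correlation between the two predictors.
#' @param n_applicants size of the applicant pool (>= 3).
#' @return An object of class `correlation_spec`.
#' @examples
#' correlation_spec(0.60, 0.20, 0.00, 1000)
#' @export
correlation_spec <- function(rho_yx1, rho_yx2, rho_x1x2, n_applicants) {
  check_number(rho_yx1, "rho_yx1", -1, 1)
  check_number(rho_yx2, "rho_yx2", -1, 1)
  check_number(rho_x1x2, "rho_x1x2", -1, 1)
  check_number(n_applicants, "n_applicants", 3, Inf)
  if (n_applicants != round(n_applicants)) {
    abort_config("`n_applicants` must be a whole number.")
  }
  R <- matrix(c(
    1, rho_x1x2, rho_yx1,
    rho_x1x2, 1, rho_yx2,
    rho_yx1, rho_yx2, 1
  ), nrow = 3, dimnames = list(c("x1", "x2", "y"), c("x1", "x2", "y")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort_config(sprintf(
      "The implied correlation matrix is not positive semidefinite (smallest eigenvalue %.3g).",
      min(ev)
    ))
  }
  structure(
    list(
      rho_yx1 = rho_yx1, rho_yx2 = rho_yx2, rho_x1x2 = rho_x1x2,
      n_applicants = as.integer(n_applicants), corr = R
    ),
    class = "correlation_spec"
  )
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat("<correlation_spec>\n")
  cat(sprintf(
    "  rho_yx1 = %.3f, rho_yx2 = %.3f, rho_x1x2 = %.3f, n = %d\n",
    x$rho_yx1, x$rho_yx2, x$rho_x1x2, x$n_applicants
  ))
  invisible(x)
}

#' Specify the compensatory selection rule
#'
#' Applicants are ranked on the composite `z = weight_x1 * x1 + weight_x2 * x2`
#' and the top fraction is admitted.  Negative weights support reversed
#' scales (e.g. German school grades, where 1.0 is best).
#'
#' @param weight_x1,weight_x2 composite weights; not both zero.
#' @param selection_rate fraction admitted, in `(0, 1]`.
#' @return An object of class `selection_design`.
#' @examples
#' selection_design(1, 1, 0.2)
#' @export
selection_design <- function(weight_x1 = 1, weight_x2 = 1, selection_rate) {
  check_number(weight_x1, "weight_x1")
  check_number(weight_x2, "weight_x2")
  if (weight_x1 == 0 && weight_x2 == 0) {
    abort_config("At least one composite weight must be nonzero.")
  }
  check_number(selection_rate, "selection_rate", 0, 1, allow_min = FALSE)
  structure(
    list(
      weight_x1 = weight_x1, weight_x2 = weight_x2,
      selection_rate = selection_rate
    ),
    class = "selection_design"
  )
}

#' @export
print.selection_design <- function(x, ...) {
  cat(sprintf(
    "<selection_design> z = %g*x1 + %g*x2, top %.0f%% admitted\n",
    x$weight_x1, x$weight_x2, 100 * x$selection_rate
  ))
  invisible(x)
}

#' Specify reliabilities for the classical-test-theory correction
#'
#' @param rel_x_applicants reliability of the predictor in the applicant
#'   pool, in `(0, 1]`.
#' @param rel_y_incumbents reliability of the outcome among incumbents, in
#'   `(0, 1]`.
#' @return An object of class `reliability_spec`.
#' @examples
#' reliability_spec(0.8, 0.7)
#' @export
reliability_spec <- function(rel_x_applicants, rel_y_incumbents) {
  check_number(rel_x_applicants, "rel_x_applicants", 0, 1, allow_min = FALSE)
  check_number(rel_y_incumbents, "rel_y_incumbents", 0, 1, allow_min = FALSE)
  structure(
    list(
      rel_x_applicants = rel_x_applicants,
      rel_y_incumbents = rel_y_incumbents
    ),
    class = "reliability_spec"
  )
}
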