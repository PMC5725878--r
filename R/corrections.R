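new_correction_estimate <- function(method, r_hat, u_used = NA_real_,
                                    inputs = list(), iterations = NA_integer_,
                                    converged = NA, diagnostics = list()) {
  if (is.finite(r_hat) && abs(r_hat) > 1) {
    warn(sprintf(
      "Corrected correlation %.4f outside [-1, 1]; clamped.", r_hat
    ))
    r_hat <- sign(r_hat)
  }
  structure(
    list(
      method = method, r_hat = r_hat, u_used = u_used, inputs = inputs,
      iterations = iterations, converged = converged, diagnostics = diagnostics
    ),
    class = "correction_estimate"
  )
}

#' @export
print.correction_estimate <- function(x, ...) {
  cat(sprintf(
    "<correction_estimate: %s>\n  corrected r = %.4f", x$method, x$r_hat
  ))
  if (is.finite(x$u_used)) cat(sprintf("  (u = %.4f)", x$u_used))
  if (!is.na(x$iterations)) {
    cat(sprintf("\n  iterations = %d, converged = %s", x$iterations, x$converged))
  }
  cat("\n")
  invisible(x)
}

#' @rdname correction_tidiers
#' @exportS3Method generics::tidy
tidy.correction_estimate <- function(x, ...) {
  tibble(
    method = x$method, r_hat = x$r_hat, u_used = x$u_used,
    iterations = x$iterations, converged = x$converged
  )
}

#' Tidiers for correction estimates
#'
#' `tidy()` returns the estimate as a one-row tibble; `glance()` adds the
#' scalar diagnostics recorded by the method (e.g. log-likelihood for the EM
#' fit, between-imputation SD for multiple imputation).
#'
#' @param x a `correction_estimate`.
#' @param ... unused.
#' @name correction_tidiers
#' @exportS3Method generics::glance
glance.correction_estimate <- function(x, ...) {
  out <- tidy(x)
  diag_scalars <- Filter(
    function(v) is.numeric(v) && length(v) == 1L, x$diagnostics
  )
  if (length(diag_scalars)) out <- dplyr::bind_cols(out, as_tibble(diag_scalars))
  out
}

#' Thorndike's case A correction for direct range restriction
#'
#' Corrects a restricted predictor-outcome correlation for selection made
#' directly on the predictor itself, given the ratio
#' `u = SD(applicants)/SD(incumbents)` of that predictor:
#' \deqn{\hat r = \frac{u\,r}{\sqrt{1 - r^2 + u^2 r^2}}.}
#' Assumes the applicant-group regression of outcome on predictor is linear
#' with homoscedastic errors.  When selection is actually on a composite
#' (indirect selection), case A systematically underestimates the
#' unrestricted correlation; see [correct_case_c()].
#'
#' @param r_i restricted correlation, in `[-1, 1]`.
#' @param u SD ratio (unrestricted / restricted), > 0.
#' @return a `correction_estimate`.
#' @examples
#' correct_case_a(0.41, 1 / 0.67) # ~0.56
#' @export
correct_case_a <- function(r_i, u) {
  check_number(r_i, "r_i", -1, 1)
  check_number(u, "u", 0, Inf, allow_min = FALSE)
  r <- u * r_i / sqrt(1 - r_i^2 + u^2 * r_i^2)
  new_correction_estimate(
    "case_a", r,
    u_used = u, inputs = list(r_i = r_i, u = u)
  )
}

#' Thorndike's case C correction for indirect (incidental) selection
#'
#' Corrects the restricted correlation between the predictor of interest and
#' the outcome when selection was made on an explicit third variable `z`
#' (here the weighted composite of the selection variables), given the
#' restricted correlations of both with `z` and the u-ratio of `z`:
#' \deqn{\hat r = \frac{r_{yx_1} + r_{zx_1} r_{zy}\,(u_z^2 - 1)}
#'   {\sqrt{1 + r_{zx_1}^2 (u_z^2 - 1)}\sqrt{1 + r_{zy}^2 (u_z^2 - 1)}}.}
#' With `u_z = 1` or a selection variable unrelated to both others it leaves
#' the input unchanged, and with `z = x1` it reduces algebraically to
#' [correct_case_a()].
#'
#' @param r_yx1_i restricted predictor-outcome correlation.
#' @param r_zx1_i restricted composite-predictor correlation.
#' @param r_zy_i restricted composite-outcome correlation.
#' @param u_z SD ratio (applicants/incumbents) of the selection variable.
#' @return a `correction_estimate`.
#' @export
correct_case_c <- function(r_yx1_i, r_zx1_i, r_zy_i, u_z) {
  check_number(r_yx1_i, "r_yx1_i", -1, 1)
  check_number(r_zx1_i, "r_zx1_i", -1, 1)
  check_number(r_zy_i, "r_zy_i", -1, 1)
  check_number(u_z, "u_z", 0, Inf, allow_min = FALSE)
  k <- u_z^2 - 1
  d1 <- 1 + r_zx1_i^2 * k
  d2 <- 1 + r_zy_i^2 * k
  if (d1 <= 0 || d2 <= 0) {
    abort_config(
      "Invalid case C inputs: a denominator factor is nonpositive (u_z < 1 with an extreme correlation)."
    )
  }
  r <- (r_yx1_i + r_zx1_i * r_zy_i * k) / sqrt(d1 * d2)
  new_correction_estimate(
    "case_c", r,
    u_used = u_z,
    inputs = list(r_yx1_i = r_yx1_i, r_zx1_i = r_zx1_i, r_zy_i = r_zy_i, u_z = u_z)
  )
}

#' Disattenuate a correlation for unreliability
#'
#' Classical-test-theory correction `r / sqrt(rel)`, estimating the
#' correlation the variable would show if measured without error.
#'
#' @param r observed correlation.
#' @param rel reliability, in `(0, 1]`.
#' @return the disattenuated correlation.
#' @examples
#' disattenuate(0.59, 0.8)
#' @export
disattenuate <- function(r, rel) {
  check_number(r, "r", -1, 1)
  check_number(rel, "rel", 0, 1, allow_min = FALSE)
  out <- r / sqrt(rel)
  if (abs(out) > 1 + 1e-12) {
    abort_config(sprintf(
      "Disattenuated correlation %.3f exceeds 1: |r| must not exceed sqrt(rel).", out
    ))
  }
  min(1, max(-1, out))
}

#' Hunter-Schmidt stepwise correction for indirect range restriction
#'
#' The classical-test-theory route to the unrestricted validity: it targets
#' the operational validity (correlation between observed predictor scores
#' and the outcome's true score in the applicant pool).  Steps, under the
#' constant-error-variance model with selection effectively on the
#' predictor's true score:
#' \enumerate{
#'   \item correct the restricted correlation for criterion unreliability:
#'     `r / sqrt(rel_y_incumbents)`;
#'   \item derive the incumbent predictor reliability
#'     `rel_x_i = 1 - (1 - rel_x_a) * u_x^2` (error variance is unaffected by
#'     selection, so the error fraction grows as the variance shrinks);
#'   \item correct for predictor unreliability: divide by `sqrt(rel_x_i)`,
#'     giving the restricted true-score correlation;
#'   \item apply the direct-restriction (case A) formula on the true-score
#'     u-ratio `u_T = u_x * sqrt(rel_x_a / rel_x_i)`;
#'   \item re-attenuate by `sqrt(rel_x_a)` to report operational validity.
#' }
#' With both reliabilities equal to 1 the chain reduces exactly to
#' [correct_case_a()].  The true-score correlation from step 4 is kept in
#' the diagnostics.
#'
#' @param r_yx1_i restricted predictor-outcome correlation.
#' @param u_x observed-score SD ratio (applicants/incumbents) of the
#'   predictor.
#' @param reliability a [reliability_spec()].
#' @return a `correction_estimate` whose `r_hat` is the operational
#'   validity; diagnostics hold `r_true_score`, `rel_x_incumbents`, `u_true`.
#' @examples
#' correct_hunter_schmidt(0.41, 1 / 0.67, reliability_spec(0.8, 0.7))
#' @export
correct_hunter_schmidt <- function(r_yx1_i, u_x, reliability) {
  check_number(r_yx1_i, "r_yx1_i", -1, 1)
  check_number(u_x, "u_x", 0, Inf, allow_min = FALSE)
  if (!inherits(reliability, "reliability_spec")) {
    abort_config("`reliability` must be a reliability_spec.")
  }
  rel_x <- reliability$rel_x_applicants
  rel_y <- reliability$rel_y_incumbents
  r1 <- r_yx1_i / sqrt(rel_y)
  rel_x_i <- 1 - (1 - rel_x) * u_x^2
  if (rel_x_i <= 0) {
    abort_config(sprintf(
      "Derived incumbent predictor reliability %.3f <= 0: u_x = %.3f is inconsistent with rel_x_applicants = %.3f.",
      rel_x_i, u_x, rel_x
    ))
  }
  r2 <- r1 / sqrt(rel_x_i)
  if (abs(r2) > 1) {
    abort_config(
      "Reliability-corrected restricted correlation exceeds 1: inputs are inconsistent with the reliability model."
    )
  }
  u_true <- u_x * sqrt(rel_x / rel_x_i)
  r_true <- correct_case_a(r2, u_true)$r_hat
  r_op <- r_true * sqrt(rel_x)
  new_correction_estimate(
    "hunter_schmidt", r_op,
    u_used = u_x,
    inputs = list(
      r_yx1_i = r_yx1_i, u_x = u_x,
      rel_x_applicants = rel_x, rel_y_incumbents = rel_y
    ),
    diagnostics = list(
      r_true_score = r_true, rel_x_incumbents = rel_x_i, u_true = u_true
    )
  )
}
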