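#' Empirical validity-correction workflow
#'
#' Runs the full correction pipeline on an applicant table in which the
#' outcome is observed only for admitted applicants: group descriptives for
#' both groups, the suppression decomposition (first-order incumbent
#' correlation, then the semipartial correlation that removes reciprocal
#' suppression), and the requested range-restriction corrections.  Case A
#' consumes the semipartial correlation and the predictor u-ratio; case C
#' consumes the composite statistics (the composite is taken from the `z`
#' column, or reconstructed from `weights` when absent); EM and multiple
#' imputation consume the table itself.
#'
#' @param data an applicant table with missing `y` for rejected applicants
#'   (or complete `y` with an explicit `selected` column, in which case
#'   every method simply returns the sample correlation).
#' @param methods subset of `c("case_a", "case_c", "em", "mice",
#'   "hunter_schmidt")`.
#' @param weights composite weights used to reconstruct `z` when the table
#'   has no `z` column.
#' @param reliability optional [reliability_spec()]; required for
#'   `"hunter_schmidt"`.
#' @param invert_u use the reciprocal of the computed predictor u-ratio in
#'   case A and the Hunter-Schmidt chain (for published ratios printed on
#'   the restricted/unrestricted scale).
#' @param case_a_r `"semipartial"` (default) or `"first_order"`: the
#'   restricted correlation case A consumes.
#' @param mice_m,mice_iterations imputation settings.
#' @param mice_pool pooling rule for the imputation estimates, `"mean"`
#'   (default) or `"fisher_z"`.
#' @param seed seed for the imputation draws.
#' @return An object of class `validity_report` with fields `descriptives`
#'   (both groups), `decomposition` (tibble), `estimates` (tibble),
#'   `fits` (the underlying `correction_estimate` objects) and `config`.
#' @examples
#' tab <- simulate_applicants(correlation_spec(.5, -.25, -.1, 700), seed = 3) |>
#'   apply_selection(selection_design(1, -1, 0.29))
#' validity_report(tab, weights = c(1, -1), seed = 1)
#' @export
validity_report <- function(data,
                            methods = c("case_a", "case_c", "em", "mice"),
                            weights = c(1, 1), reliability = NULL,
                            invert_u = FALSE,
                            case_a_r = c("semipartial", "first_order"),
                            mice_m = 20, mice_iterations = 10,
                            mice_pool = c("mean", "fisher_z"), seed = NULL) {
  mice_pool <- match.arg(mice_pool)
  case_a_r <- match.arg(case_a_r)
  methods <- match.arg(
    methods,
    c("case_a", "case_c", "em", "mice", "hunter_schmidt"),
    several.ok = TRUE
  )
  had_selected <- is.data.frame(data) && "selected" %in% names(data)
  data <- as_applicant_table(data)
  complete <- !anyNA(data$y)
  if (complete && !had_selected) {
    abort_config("Nothing to correct: `y` is complete and no selected/rejected split is given.")
  }
  if (sum(data$selected) < 3) abort_data("Fewer than 3 incumbents.")
  if (!"z" %in% names(data)) {
    data$z <- weights[1] * data$x1 + weights[2] * data$x2
  }
  desc_i <- describe_group(data, "incumbents")
  desc_a <- describe_group(data, "applicants")

  r_first <- desc_i$corr["x1", "y"]
  r_semi <- semipartial_r(
    r_first, desc_i$corr["x2", "y"], desc_i$corr["x1", "x2"]
  )
  u_x <- desc_a$sds["x1"] / desc_i$sds["x1"]
  u_z <- desc_a$sds["z"] / desc_i$sds["z"]
  if (invert_u) u_x <- 1 / u_x

  fits <- list()
  if ("case_a" %in% methods) {
    r_in <- if (case_a_r == "semipartial") r_semi else r_first
    fits$case_a <- if (complete) {
      new_correction_estimate("case_a", r_first, u_used = 1)
    } else {
      correct_case_a(r_in, u_x)
    }
  }
  if ("case_c" %in% methods) {
    fits$case_c <- if (complete) {
      new_correction_estimate("case_c", r_first, u_used = 1)
    } else {
      correct_case_c(
        r_first, desc_i$corr["z", "x1"], desc_i$corr["z", "y"], u_z
      )
    }
  }
  if ("em" %in% methods) fits$em <- fit_em(data)
  if ("mice" %in% methods) {
    fits$mice <- fit_mice(data, m = mice_m, iterations = mice_iterations,
      seed = seed, pool = mice_pool)
  }
  if ("hunter_schmidt" %in% methods) {
    if (is.null(reliability)) {
      abort_config("`reliability` is required for the hunter_schmidt method.")
    }
    fits$hunter_schmidt <- if (complete) {
      new_correction_estimate("hunter_schmidt", r_first, u_used = 1)
    } else {
      correct_hunter_schmidt(r_semi, u_x, reliability)
    }
  }
  estimates <- dplyr::bind_rows(lapply(fits, tidy))
  best <- intersect(c("case_c", "em", "mice"), estimates$method)
  decomposition <- tibble(
    step = c("first_order", "semipartial", "range_corrected"),
    description = c(
      "incumbent correlation r_yx1|i",
      "suppression removed: r_yx1.2|i",
      if (length(best)) {
        sprintf("indirect-restriction corrected (%s)", best[1])
      } else "indirect-restriction corrected (none requested)"
    ),
    r = c(
      r_first, r_semi,
      if (length(best)) estimates$r_hat[estimates$method == best[1]] else NA_real_
    )
  )
  structure(
    list(
      descriptives = list(applicants = desc_a, incumbents = desc_i),
      decomposition = decomposition,
      estimates = estimates,
      fits = fits,
      config = list(
        methods = methods, weights = weights, invert_u = invert_u,
        case_a_r = case_a_r, u_x = unname(u_x), u_z = unname(u_z),
        mice_m = mice_m, mice_iterations = mice_iterations,
        mice_pool = mice_pool, seed = seed
      )
    ),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "<validity_report: %d applicants, %d incumbents>\n",
    x$descriptives$applicants$n, x$descriptives$incumbents$n
  ))
  cat(sprintf(
    "u(x1) = %.3f, u(z) = %.3f%s\n",
    x$config$u_x, x$config$u_z,
    if (x$config$invert_u) " [u inverted by request]" else ""
  ))
  cat("\nSuppression / restriction decomposition:\n")
  print(as.data.frame(x$decomposition), digits = 3, row.names = FALSE)
  cat("\nCorrected validity estimates:\n")
  print(as.data.frame(x$estimates), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.validity_report <- function(x, ...) x$estimates
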