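#' Descriptive statistics for applicants or incumbents
#'
#' Computes per-variable means, standard deviations (n-1 convention) and the
#' Pearson correlation matrix within the requested group.  For the applicant
#' group the outcome `y` is typically observed only in the selected subgroup;
#' y-involving statistics are then computed over the observed-y rows only and
#' flagged via `y_complete = FALSE` — they are never silently pooled.
#' Zero-variance columns are flagged degenerate and their correlations
#' reported as `NA`.
#'
#' @param data an applicant table, see [as_applicant_table()].
#' @param group `"applicants"` (all rows) or `"incumbents"` (selected rows).
#' @return An object of class `group_descriptives` with fields `group`, `n`,
#'   `n_y_observed`, `y_complete`, `means`, `sds`, `corr`, `degenerate`.
#' @examples
#' tab <- simulate_applicants(correlation_spec(.6, .2, 0, 500), seed = 1) |>
#'   apply_selection(selection_design(1, 1, 0.2))
#' describe_group(tab, "incumbents")
#' @export
describe_group <- function(data, group = c("applicants", "incumbents")) {
  group <- match.arg(group)
  data <- as_applicant_table(data)
  rows <- if (group == "incumbents") data[data$selected, , drop = FALSE] else data
  if (nrow(rows) == 0) abort_data(sprintf("Group '%s' is empty.", group))
  if (nrow(rows) < 3) {
    abort_data(sprintf(
      "Group '%s' has %d row(s); at least 3 are required.", group, nrow(rows)
    ))
  }
  vars <- intersect(c("x1", "x2", "z", "y"), names(rows))
  M <- as.matrix(rows[vars])
  if (group == "incumbents" && anyNA(M[, "y"])) {
    abort_data("Outcome `y` must be complete within the incumbents.")
  }
  y_obs <- !is.na(M[, "y"])
  means <- colMeans(M, na.rm = TRUE)
  sds <- apply(M, 2, sd, na.rm = TRUE)
  degenerate <- names(sds)[sds == 0]
  if (length(degenerate)) {
    warn(sprintf(
      "Zero-variance column(s) %s: correlations reported as NA.",
      paste0("`", degenerate, "`", collapse = ", ")
    ))
  }
  corr <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  corr[degenerate, ] <- NA_real_
  corr[, degenerate] <- NA_real_
  diag(corr) <- ifelse(vars %in% degenerate, NA_real_, 1)
  structure(
    list(
      group = group,
      n = nrow(rows),
      n_y_observed = sum(y_obs),
      y_complete = all(y_obs),
      means = means,
      sds = sds,
      corr = corr,
      degenerate = degenerate
    ),
    class = "group_descriptives"
  )
}

#' @export
print.group_descriptives <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<group_descriptives: %s, n = %d%s>\n", x$group, x$n,
    if (!x$y_complete) {
      sprintf(", y observed for %d rows only", x$n_y_observed)
    } else ""
  ))
  stats <- rbind(mean = x$means, sd = x$sds)
  print(round(stats, digits))
  cat("correlations:\n")
  print(round(x$corr, digits))
  invisible(x)
}

#' @describeIn describe_group long-format tibble of the pairwise
#'   correlations together with each variable's mean and SD.
#' @param x a `group_descriptives` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.group_descriptives <- function(x, ...) {
  vars <- colnames(x$corr)
  pairs <- which(upper.tri(x$corr), arr.ind = TRUE)
  tibble(
    group = x$group,
    var1 = vars[pairs[, 1]],
    var2 = vars[pairs[, 2]],
    r = x$corr[pairs],
    n = ifelse(vars[pairs[, 1]] == "y" | vars[pairs[, 2]] == "y",
      x$n_y_observed, x$n
    )
  )
}

#' Ratio of unrestricted to restricted standard deviation
#'
#' The u-ratio `SD(applicants) / SD(incumbents)` of a variable is the key
#' input to the range-restriction corrections.  Under genuine restriction it
#' exceeds 1; a value below 1 triggers a warning (it usually indicates that
#' the two groups were swapped or that a published ratio was printed on the
#' reciprocal scale), never an automatic inversion.
#'
#' @param desc_applicants,desc_incumbents `group_descriptives` for the
#'   unrestricted and restricted group.
#' @param variable variable name, default `"x1"`.
#' @return the ratio, a positive number.
#' @export
u_ratio <- function(desc_applicants, desc_incumbents, variable = "x1") {
  sd_a <- desc_applicants$sds[[variable]]
  sd_i <- desc_incumbents$sds[[variable]]
  if (is.null(sd_a) || is.null(sd_i)) {
    abort_config(sprintf("Variable `%s` not present in both groups.", variable))
  }
  if (sd_i <= 0) abort_data("Restricted SD is zero; the u-ratio is undefined.")
  if (sd_a <= 0) abort_data("Unrestricted SD is zero; the u-ratio is undefined.")
  u <- sd_a / sd_i
  if (u < 1) {
    warn(sprintf(
      "u = %.3f < 1: the 'unrestricted' group has the smaller SD of `%s`. Check group roles or use the reciprocal explicitly.",
      u, variable
    ))
  }
  u
}

#' Semipartial correlation of the outcome with a residualized predictor
#'
#' Correlation between `y` and the residual of `x1` after the linear effect
#' of `x2` is removed from `x1` only:
#' `(r_yx1 - r_yx2 * r_x1x2) / sqrt(1 - r_x1x2^2)`.
#' This removes the reciprocal-suppression artifact that compensatory
#' selection induces via a negative incumbent predictor intercorrelation.
#' Bounded in `[-1, 1]`, unlike the standardized regression weight.
#'
#' @param r_yx1,r_yx2,r_x1x2 pairwise correlations; `|r_x1x2| < 1`.
#' @return the semipartial correlation.
#' @examples
#' semipartial_r(0.37, -0.124, -0.71) # ~0.40
#' @export
semipartial_r <- function(r_yx1, r_yx2, r_x1x2) {
  check_number(r_yx1, "r_yx1", -1, 1)
  check_number(r_yx2, "r_yx2", -1, 1)
  check_number(r_x1x2, "r_x1x2", -1, 1, allow_min = FALSE, allow_max = FALSE)
  unname((r_yx1 - r_yx2 * r_x1x2) / sqrt(1 - r_x1x2^2))
}

#' Standardized regression weights for two predictors
#'
#' Beta weights of the regression of `y` on standardized `x1`, `x2`.  These
#' are weights, not correlations: they may exceed 1 in magnitude.  Each beta
#' equals the corresponding semipartial correlation divided by
#' `sqrt(1 - r_x1x2^2)`.
#'
#' @inheritParams semipartial_r
#' @return named numeric vector `c(beta_x1, beta_x2)`.
#' @examples
#' beta_weights(0.5, 0.5, -0.5) # both 1.0
#' @export
beta_weights <- function(r_yx1, r_yx2, r_x1x2) {
  check_number(r_x1x2, "r_x1x2", -1, 1, allow_min = FALSE, allow_max = FALSE)
  d <- 1 - r_x1x2^2
  c(
    beta_x1 = unname((r_yx1 - r_yx2 * r_x1x2) / d),
    beta_x2 = unname((r_yx2 - r_yx1 * r_x1x2) / d)
  )
}

#' Residualize one predictor on the other within a group
#'
#' Least-squares residuals of `target` regressed on `covariate`, fit within
#' the requested group.  The residual of a row is its observed target value
#' minus the value the within-group regression line predicts from the
#' covariate.  Residuals have zero mean and zero correlation with the
#' covariate within the fitting group.
#'
#' @inheritParams describe_group
#' @param target,covariate column names, default `"x1"` on `"x2"`.
#' @return the group's rows with an added `.resid` column.
#' @export
residualize <- function(data, target = "x1", covariate = "x2",
                        group = c("incumbents", "applicants")) {
  group <- match.arg(group)
  data <- as_applicant_table(data)
  rows <- if (group == "incumbents") data[data$selected, , drop = FALSE] else data
  if (nrow(rows) == 0) abort_data(sprintf("Group '%s' is empty.", group))
  xv <- rows[[covariate]]
  yv <- rows[[target]]
  if (is.null(xv) || is.null(yv)) abort_config("Unknown target/covariate column.")
  if (sd(xv) == 0) abort_data(sprintf("Covariate `%s` is constant within '%s'.", covariate, group))
  slope <- cov(xv, yv) / var(xv)
  rows$.resid <- yv - (mean(yv) + slope * (xv - mean(xv)))
  rows
}
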