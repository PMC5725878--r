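#' Summarize estimation errors across replications
#'
#' @param errors numeric vector of per-replication estimation errors
#'   (estimate minus reference).
#' @return a one-row tibble with `n`, `mean`, `sd` (n-1), `rmse`
#'   (`sqrt(mean(errors^2))`, i.e. including bias), and the empirical 2.5th
#'   and 97.5th percentiles `ci_low`, `ci_high`.  By construction
#'   `rmse^2 = mean^2 + sd^2 * (n-1)/n`.
#' @examples
#' summarize_errors(c(0.1, -0.1))
#' @export
summarize_errors <- function(errors) {
  if (!is.numeric(errors) || length(errors) == 0) {
    abort_config("`errors` must be a nonempty numeric vector.")
  }
  tibble(
    n = length(errors),
    mean = mean(errors),
    sd = if (length(errors) > 1) sd(errors) else 0,
    rmse = sqrt(mean(errors^2)),
    ci_low = unname(quantile(errors, 0.025, type = 7)),
    ci_high = unname(quantile(errors, 0.975, type = 7))
  )
}

# One replication: generate, select, compute every requested estimate.
# Returns estimates and the realized applicant-sample correlation.
study_rep <- function(spec, design, methods, case_a_u, mice_m, mice_iterations,
                      em_tolerance, em_max_iterations) {
  X <- MASS::mvrnorm(spec$n_applicants, c(0, 0, 0), spec$corr)
  x1 <- X[, 1]; x2 <- X[, 2]; y <- X[, 3]
  r_realized <- cor(x1, y)
  z <- design$weight_x1 * x1 + design$weight_x2 * x2
  k <- ceiling(design$selection_rate * length(z))
  sel <- rank(-z, ties.method = "first") <= k
  i <- which(sel)
  ymask <- y
  ymask[!sel] <- NA_real_

  r_yx1_i <- cor(x1[i], y[i])
  est <- c()
  if ("case_a" %in% methods) {
    r_yx2_i <- cor(x2[i], y[i])
    r_x1x2_i <- cor(x1[i], x2[i])
    sp <- (r_yx1_i - r_yx2_i * r_x1x2_i) / sqrt(1 - r_x1x2_i^2)
    u <- if (case_a_u == "residual") {
      # residuals of x1 on x2 fit within each group separately
      res_a <- x1 - mean(x1) - cov(x1, x2) / var(x2) * (x2 - mean(x2))
      xi1 <- x1[i]; xi2 <- x2[i]
      res_i <- xi1 - mean(xi1) - cov(xi1, xi2) / var(xi2) * (xi2 - mean(xi2))
      sd(res_a) / sd(res_i)
    } else {
      sd(x1) / sd(x1[i])
    }
    est["case_a"] <- correct_case_a(sp, u)$r_hat
  }
  if ("case_c" %in% methods) {
    est["case_c"] <- correct_case_c(
      r_yx1_i, cor(z[i], x1[i]), cor(z[i], y[i]), sd(z) / sd(z[i])
    )$r_hat
  }
  if ("em" %in% methods) {
    pc <- em_precompute(x1, x2, ymask)
    fit <- em_iterate(pc, em_max_iterations, em_tolerance, FALSE)
    est["em"] <- fit$corr[1, 3]
  }
  if ("mice" %in% methods) {
    est["mice"] <- mice_core(x1, x2, ymask,
      m = mice_m, iterations = mice_iterations, pool = "mean"
    )$r_hat
  }
  list(estimates = est, r_realized = r_realized)
}

#' Monte Carlo comparison of range-restriction correction methods
#'
#' Repeats the generate / select / correct cycle and scores each method by
#' its estimation error, the difference between the corrected correlation
#' and the reference.  By default the reference is the realized
#' applicant-sample correlation of each replication (the quantity the
#' generating process makes knowable); `error_reference = "population"`
#' scores against the specified population value instead.
#'
#' Within the harness, case A consumes the incumbent semipartial correlation
#' (the predictor residualized on its companion) together with the raw
#' predictor u-ratio; case C consumes the realized composite statistics; EM
#' and multiple imputation consume the masked table.
#'
#' @param spec a [correlation_spec()].
#' @param rates selection fractions to study, each in `(0, 1)`.
#' @param n_reps replications per rate (default 1000).
#' @param methods subset of `c("case_a", "case_c", "em", "mice")`.
#' @param weights composite weights `c(w1, w2)` (default equal).
#' @param seed top-level seed; per-replication child seeds are derived via
#'   [split_seed()] so any replication is reproducible in isolation.
#' @param error_reference `"realized"` (default) or `"population"`.
#' @param case_a_u `"raw"` (default; u-ratio of the raw predictor) or
#'   `"residual"` (u-ratio of the within-group residualized predictor).
#' @param mice_m,mice_iterations imputation settings (defaults 20 and 10).
#' @param em_tolerance,em_max_iterations EM settings.
#' @return An object of class `validity_study`: a list with `summary`
#'   (tibble: method, rate, mean, sd, rmse, ci_low, ci_high, n_reps,
#'   n_failed), `errors` (tibble of per-replication errors), and `config`.
#' @examples
#' run_validity_study(correlation_spec(.6, .2, 0, 200),
#'   rates = 0.3, n_reps = 20, methods = c("case_a", "case_c"), seed = 1
#' )
#' @export
run_validity_study <- function(spec, rates = c(0.3, 0.2, 0.1), n_reps = 1000,
                               methods = c("case_a", "case_c", "em", "mice"),
                               weights = c(1, 1), seed = NULL,
                               error_reference = c("realized", "population"),
                               case_a_u = c("raw", "residual"),
                               mice_m = 20, mice_iterations = 10,
                               em_tolerance = 1e-8, em_max_iterations = 5000) {
  error_reference <- match.arg(error_reference)
  case_a_u <- match.arg(case_a_u)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!inherits(spec, "correlation_spec")) {
    abort_config("`spec` must be a correlation_spec.")
  }
  check_number(n_reps, "n_reps", 1, Inf)
  for (r in rates) check_number(r, "rates", 0, 1, allow_min = FALSE, allow_max = FALSE)

  child_seeds <- matrix(
    split_seed(seed, n_reps * length(rates)),
    nrow = n_reps
  )
  rows <- vector("list", length(rates))
  failures <- stats::setNames(rep(0L, length(rates)), as.character(rates))
  for (ri in seq_along(rates)) {
    design <- selection_design(weights[1], weights[2], rates[ri])
    E <- matrix(NA_real_, n_reps, length(methods),
      dimnames = list(NULL, methods)
    )
    refs <- numeric(n_reps)
    for (rep in seq_len(n_reps)) {
      set.seed(child_seeds[rep, ri])
      res <- tryCatch(
        study_rep(
          spec, design, methods, case_a_u, mice_m, mice_iterations,
          em_tolerance, em_max_iterations
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[ri] <- failures[ri] + 1L
        warn(sprintf(
          "Replication %d at rate %.2f failed: %s", rep, rates[ri],
          conditionMessage(res)
        ))
        next
      }
      ref <- if (error_reference == "realized") res$r_realized else spec$rho_yx1
      E[rep, names(res$estimates)] <- res$estimates - ref
      refs[rep] <- ref
    }
    ok <- !is.na(E[, 1])
    rows[[ri]] <- tibble(
      rate = rates[ri],
      rep = rep(which(ok), times = length(methods)),
      method = rep(methods, each = sum(ok)),
      error = as.vector(E[ok, , drop = FALSE]),
      reference = rep(refs[ok], times = length(methods))
    )
  }
  errors <- dplyr::bind_rows(rows)
  summary <- errors |>
    dplyr::group_by(.data$method, .data$rate) |>
    dplyr::reframe(summarize_errors(.data$error)) |>
    dplyr::rename(n_reps = "n") |>
    dplyr::mutate(n_failed = failures[as.character(.data$rate)]) |>
    dplyr::arrange(.data$method, dplyr::desc(.data$rate))
  structure(
    list(
      summary = summary, errors = errors,
      config = list(
        spec = spec, rates = rates, n_reps = n_reps, methods = methods,
        weights = weights, seed = seed, error_reference = error_reference,
        case_a_u = case_a_u, mice_m = mice_m,
        mice_iterations = mice_iterations
      )
    ),
    class = "validity_study"
  )
}

#' @export
print.validity_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<validity_study: %d reps x rates {%s}, reference = %s>\n",
    cfg$n_reps, paste(cfg$rates, collapse = ", "), cfg$error_reference
  ))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname study_tidiers
#' @exportS3Method generics::tidy
tidy.validity_study <- function(x, ...) x$summary

#' Tidiers for Monte Carlo studies
#'
#' `tidy()` returns the per-method, per-rate summary (mean error, SD, RMSE,
#' percentile interval); `glance()` a one-row description of the run.
#'
#' @param x a `validity_study`.
#' @param ... unused.
#' @name study_tidiers
#' @exportS3Method generics::glance
glance.validity_study <- function(x, ...) {
  tibble(
    n_reps = x$config$n_reps,
    n_rates = length(x$config$rates),
    n_methods = length(x$config$methods),
    n_failed = sum(unique(x$summary[c("rate", "n_failed")])$n_failed),
    error_reference = x$config$error_reference
  )
}

#' Plot the error distributions of a Monte Carlo study
#'
#' Boxplots of per-replication estimation errors by method, faceted by
#' selection rate, with a reference line at zero error.
#'
#' @param object a `validity_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.validity_study <- function(object, ...) {
  ggplot2::ggplot(
    object$errors,
    ggplot2::aes(.data$method, .data$error)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(
      ~rate,
      labeller = ggplot2::labeller(rate = function(v) paste0(100 * as.numeric(v), "% selected"))
    ) +
    ggplot2::labs(x = NULL, y = "estimation error (corrected r - reference r)") +
    ggplot2::theme_minimal()
}
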