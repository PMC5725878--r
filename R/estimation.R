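# Likelihood-based and imputation-based estimation of the unrestricted
# predictor-outcome correlation from an applicant table whose outcome is
# missing exactly for rejected applicants (MAR given x1, x2, since rejection
# is a deterministic function of the observed predictors).

# Shared precomputation.  Because only y is ever missing (a monotone
# pattern) and E[y | x] is linear under the normal model, every E-step
# reduces to closed-form combinations of fixed cross-products; the EM loop
# below therefore costs O(1) per iteration after this O(n) pass.
em_precompute <- function(x1, x2, y) {
  miss <- is.na(y)
  obs <- !miss
  X <- cbind(x1, x2)
  O <- cbind(x1[obs], x2[obs], y[obs])
  list(
    n = length(y), n_obs = sum(obs), n_mis = sum(miss),
    Sx = colSums(X), Qx = crossprod(X),
    So = colSums(O), Qo = crossprod(O),
    Sm = colSums(X[miss, , drop = FALSE]),
    Qm = crossprod(X[miss, , drop = FALSE])
  )
}

# Observed-data log-likelihood: trivariate normal for complete rows plus
# bivariate normal (x1, x2) for rows with missing y, evaluated from the
# group cross-products.
em_loglik <- function(pc, mu, S) {
  ll_block <- function(Q, s, n, mu, S) {
    p <- length(mu)
    C <- Q - tcrossprod(s, mu) - tcrossprod(mu, s) + n * tcrossprod(mu)
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    -0.5 * (n * (p * log(2 * pi) + logdet) + sum(diag(chol2inv(ch) %*% C)))
  }
  ll <- ll_block(pc$Qo, pc$So, pc$n_obs, mu, S)
  if (pc$n_mis > 0) {
    ll <- ll + ll_block(pc$Qm, pc$Sm, pc$n_mis, mu[1:2], S[1:2, 1:2])
  }
  ll
}

em_iterate <- function(pc, max_iterations, tolerance, report_loglik) {
  n <- pc$n
  # start from all-row predictor moments and observed-row outcome moments
  mu <- c(pc$Sx / n, pc$So[3] / pc$n_obs)
  S <- matrix(0, 3, 3)
  S[1:2, 1:2] <- pc$Qx / n - tcrossprod(mu[1:2])
  Co <- pc$Qo / pc$n_obs - tcrossprod(pc$So / pc$n_obs)
  S[3, ] <- S[, 3] <- c(Co[3, 1], Co[3, 2], Co[3, 3])
  loglik <- if (report_loglik) numeric(0) else NULL
  converged <- FALSE
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    if (report_loglik) loglik <- c(loglik, em_loglik(pc, mu, S))
    # E-step: regression of y on (x1, x2) under current parameters
    Sxx <- S[1:2, 1:2]
    ch <- tryCatch(chol(Sxx), error = function(e) NULL)
    if (is.null(ch)) abort_data("Singular predictor covariance during EM.")
    b <- chol2inv(ch) %*% S[1:2, 3]
    v <- S[3, 3] - sum(b * S[1:2, 3])
    a <- mu[3] - sum(b * mu[1:2])
    sum_ey <- pc$n_mis * a + sum(b * pc$Sm)
    sum_eyx <- a * pc$Sm + drop(pc$Qm %*% b)
    sum_ey2 <- pc$n_mis * a^2 + 2 * a * sum(b * pc$Sm) +
      drop(crossprod(b, pc$Qm %*% b)) + pc$n_mis * v
    # M-step from completed sufficient statistics (ML convention, /n)
    T1 <- c(pc$Sx, pc$So[3] + sum_ey)
    T2 <- matrix(0, 3, 3)
    T2[1:2, 1:2] <- pc$Qx
    T2[1:2, 3] <- T2[3, 1:2] <- pc$Qo[1:2, 3] + sum_eyx
    T2[3, 3] <- pc$Qo[3, 3] + sum_ey2
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    delta <- max(abs(c(
      mu_new - mu,
      cov2cor(S_new) - cov2cor(S),
      sqrt(diag(S_new)) - sqrt(diag(S))
    )))
    mu <- mu_new
    S <- S_new
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iterations) break
  }
  list(
    mu = mu, sigma = S, corr = cov2cor(S),
    iterations = iterations, converged = converged, loglik = loglik
  )
}

#' Maximum likelihood estimation of the unrestricted correlation via EM
#'
#' Fits the trivariate normal model for `(x1, x2, y)` over the whole
#' applicant pool by expectation-maximization, treating the outcomes of
#' rejected applicants as missing at random given the predictors.  The
#' E-step replaces each missing outcome's first and second moments by their
#' conditional expectations under the current parameters (including the
#' residual variance in `E[y^2 | x]`); the M-step recomputes the mean vector
#' and covariance matrix; iteration stops when no parameter (mean, SD or
#' correlation scale) changes by more than `tolerance`.  The returned
#' estimate is the correlation of `x1` and `y` implied by the converged
#' covariance matrix.
#'
#' @param data an applicant table; at least 3 incumbents, predictors
#'   complete.
#' @param max_iterations iteration cap (default 5000).
#' @param tolerance convergence threshold on the maximum absolute parameter
#'   change (default 1e-8).
#' @param report_loglik record the observed-data log-likelihood at each
#'   iteration (guaranteed non-decreasing) in the diagnostics.
#' @return a `correction_estimate` (method `"em"`) with the fitted mean
#'   vector, covariance and correlation matrices in the diagnostics.
#' @examples
#' tab <- simulate_applicants(correlation_spec(.6, .2, 0, 400), seed = 7) |>
#'   apply_selection(selection_design(1, 1, 0.3))
#' fit_em(tab)
#' @export
fit_em <- function(data, max_iterations = 5000, tolerance = 1e-8,
                   report_loglik = FALSE) {
  check_number(max_iterations, "max_iterations", 1, Inf)
  check_number(tolerance, "tolerance", 0, Inf, allow_min = FALSE)
  data <- as_applicant_table(data)
  obs <- !is.na(data$y)
  if (sum(obs) < 3) abort_data("At least 3 incumbents are required.")
  if (!any(!obs)) {
    # complete data: ML estimates are the sample moments, one pass
    S <- cov(cbind(data$x1, data$x2, data$y)) * (nrow(data) - 1) / nrow(data)
    return(new_correction_estimate(
      "em", cov2cor(S)[1, 3],
      iterations = 1L, converged = TRUE,
      diagnostics = list(
        mu = colMeans(cbind(data$x1, data$x2, data$y)), sigma = S,
        n = nrow(data), n_missing = 0L
      )
    ))
  }
  pc <- em_precompute(data$x1, data$x2, data$y)
  ch <- tryCatch(
    chol(pc$Qo / pc$n_obs - tcrossprod(pc$So / pc$n_obs)),
    error = function(e) NULL
  )
  if (is.null(ch)) abort_data("Singular incumbent covariance matrix.")
  fit <- em_iterate(pc, max_iterations, tolerance, report_loglik)
  if (!fit$converged) {
    warn(sprintf(
      "EM did not converge within %d iterations (returning current estimate).",
      as.integer(max_iterations)
    ))
  }
  diagnostics <- list(
    mu = fit$mu, sigma = fit$sigma, corr = fit$corr,
    n = pc$n, n_missing = pc$n_mis
  )
  if (report_loglik) {
    diagnostics$loglik_trace <- fit$loglik
    diagnostics$loglik <- fit$loglik[length(fit$loglik)]
  }
  new_correction_estimate(
    "em", fit$corr[1, 3],
    iterations = fit$iterations, converged = fit$converged,
    diagnostics = diagnostics
  )
}

#' Pearson-Lawley closed-form correction (multivariate selection)
#'
#' The closed-form counterpart of [fit_em()]: regress `y` on `(x1, x2)`
#' within the incumbents, then propagate the regression coefficients and
#' residual variance through the applicant-pool predictor covariance to
#' obtain the implied unrestricted covariance of `y` with the predictors.
#' Under joint normality with selection a function of `(x1, x2)`, maximum
#' likelihood with missing-at-random outcomes coincides with this
#' correction, which makes the two mutually checkable to numerical
#' precision.
#'
#' @param x an applicant table, or a `group_descriptives` of the incumbents
#'   (full trivariate) if `desc_applicants` is supplied.
#' @param desc_applicants `group_descriptives` of the applicant pool (its
#'   `x1`, `x2` statistics are used); ignored when `x` is a data frame.
#' @return a `correction_estimate` (method `"lawley"`).
#' @export
lawley_correct <- function(x, desc_applicants = NULL) {
  if (is.data.frame(x)) {
    tab <- as_applicant_table(x)
    desc_i <- describe_group(tab, "incumbents")
    desc_a <- describe_group(tab, "applicants")
  } else if (inherits(x, "group_descriptives")) {
    if (is.null(desc_applicants)) {
      abort_config("Supply `desc_applicants` alongside incumbent descriptives.")
    }
    desc_i <- x
    desc_a <- desc_applicants
  } else {
    abort_config("`x` must be an applicant table or group_descriptives.")
  }
  vars <- c("x1", "x2")
  # ML (/n) covariance scaling so the closed form is the exact fixed point
  # of the EM iteration (the correlation is not invariant to mixing /n and
  # /(n-1) between the incumbent residual variance and the applicant
  # predictor covariance)
  cov_from_desc <- function(d, vars) {
    s <- d$sds[vars]
    d$corr[vars, vars] * tcrossprod(s) * (d$n - 1) / d$n
  }
  f_i <- (desc_i$n - 1) / desc_i$n
  Sxx_i <- cov_from_desc(desc_i, vars)
  Sxy_i <- desc_i$corr["y", vars] * desc_i$sds["y"] * desc_i$sds[vars] * f_i
  Syy_i <- desc_i$sds["y"]^2 * f_i
  ch <- tryCatch(chol(Sxx_i), error = function(e) NULL)
  if (is.null(ch)) abort_data("Singular incumbent predictor covariance.")
  b <- drop(chol2inv(ch) %*% Sxy_i)
  v <- Syy_i - sum(b * Sxy_i)
  Sxx_a <- cov_from_desc(desc_a, vars)
  Sxy_a <- drop(Sxx_a %*% b)
  Syy_a <- v + sum(b * Sxy_a)
  r <- unname(Sxy_a[1] / sqrt(Sxx_a[1, 1] * Syy_a))
  new_correction_estimate(
    "lawley", r,
    inputs = list(slopes = b, residual_var = v),
    diagnostics = list(implied_var_y = Syy_a, implied_cov_x1y = Sxy_a[1])
  )
}

# Fast internal worker shared by fit_mice() and the Monte Carlo harness.
# Proper Bayesian imputation with a normal linear regression of y on
# (x1, x2): the model posterior is estimated on the observed-y rows (the
# predictors are complete, so the chained-equations loop is a single
# conditional model); each sweep redraws the residual variance from its
# scaled inverse-chi-square posterior, the coefficients from their
# conditional normal posterior, and the missing outcomes from the posterior
# predictive.
mice_core <- function(x1, x2, y, m, iterations, pool) {
  n <- length(y)
  mi <- which(is.na(y))
  o <- which(!is.na(y))
  X <- cbind(1, x1, x2)
  Xo <- X[o, , drop = FALSE]
  yo <- y[o]
  ch <- tryCatch(chol(crossprod(Xo)), error = function(e) NULL)
  if (is.null(ch)) abort_data("Singular design matrix in the imputation model.")
  XtXinv <- chol2inv(ch)
  Rt <- t(chol(XtXinv))
  bhat <- XtXinv %*% crossprod(Xo, yo)
  sse <- sum((yo - Xo %*% bhat)^2)
  df <- length(o) - 3L
  if (df <= 0) abort_data("Too few incumbents for the imputation model.")
  Xm <- X[mi, , drop = FALSE]
  nm <- length(mi)
  est <- numeric(m)
  for (j in seq_len(m)) {
    yy <- y
    for (s in seq_len(iterations)) {
      sig2 <- sse / rchisq(1, df)
      beta <- bhat + sqrt(sig2) * (Rt %*% rnorm(3))
      yy[mi] <- drop(Xm %*% beta) + rnorm(nm, 0, sqrt(sig2))
    }
    est[j] <- cor(x1, yy)
  }
  pooled <- if (pool == "fisher_z") tanh(mean(atanh(est))) else mean(est)
  list(r_hat = pooled, estimates = est, between_sd = sd(est))
}

#' Multiple imputation by chained equations
#'
#' Estimates the unrestricted predictor-outcome correlation in three phases.
#' Imputation: `m` completed datasets are generated by proper Bayesian
#' imputation of the missing outcomes under a normal linear regression of
#' `y` on `(x1, x2)` (posterior draws of coefficients and residual variance,
#' then posterior-predictive draws of the missing values).  Analysis: the
#' `x1`-`y` correlation is computed over all rows of each completed dataset.
#' Pooling: the `m` correlations are averaged arithmetically (optionally on
#' the Fisher-z scale).  Since only the outcome is ever missing, the chained
#' loop involves a single conditional model and mixes immediately; the
#' `iterations` sweeps simply redraw from the same posterior.
#'
#' @param data an applicant table.
#' @param m number of imputed datasets (>= 2, default 20).
#' @param iterations sweeps per dataset (default 10).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param pool `"mean"` (arithmetic average of correlations, the default) or
#'   `"fisher_z"`.
#' @return a `correction_estimate` (method `"mice"`); diagnostics hold the
#'   per-dataset estimates and their between-imputation SD.
#' @examples
#' tab <- simulate_applicants(correlation_spec(.6, .2, 0, 400), seed = 7) |>
#'   apply_selection(selection_design(1, 1, 0.3))
#' fit_mice(tab, m = 10, seed = 1)
#' @export
fit_mice <- function(data, m = 20, iterations = 10, seed = NULL,
                     pool = c("mean", "fisher_z")) {
  pool <- match.arg(pool)
  check_number(m, "m", 2, Inf)
  check_number(iterations, "iterations", 1, Inf)
  data <- as_applicant_table(data)
  if (sum(!is.na(data$y)) < 3) abort_data("At least 3 incumbents are required.")
  if (!anyNA(data$y)) {
    # nothing to impute: every completed dataset is the data itself
    return(new_correction_estimate(
      "mice", cor(data$x1, data$y),
      iterations = as.integer(iterations), converged = TRUE,
      diagnostics = list(m = as.integer(m), between_sd = 0)
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- mice_core(data$x1, data$x2, data$y, m = m, iterations = iterations,
    pool = pool)
  new_correction_estimate(
    "mice", res$r_hat,
    iterations = as.integer(iterations), converged = TRUE,
    diagnostics = list(
      m = as.integer(m), estimates = res$estimates,
      between_sd = res$between_sd, seed = seed
    )
  )
}
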