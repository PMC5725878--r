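test_that("with complete data both estimators return the sample correlation", {
  tab <- masked_table(150, 1, seed = 41) # selection rate 1: nobody rejected
  r <- cor(tab$x1, tab$y)
  em <- fit_em(tab)
  expect_equal(em$r_hat, r)
  expect_equal(em$iterations, 1L)
  expect_true(em$converged)
  mi <- fit_mice(tab, seed = 1)
  expect_equal(mi$r_hat, r)
  expect_equal(mi$diagnostics$between_sd, 0)
})

test_that("EM agrees with the Pearson-Lawley closed form", {
  # heavy missingness: 60% of outcomes masked
  tab <- masked_table(50, 0.4, seed = 42)
  em <- fit_em(tab)
  lw <- lawley_correct(tab)
  expect_true(em$converged)
  expect_equal(em$r_hat, lw$r_hat, tolerance = 1e-4)
  # and on several other instances (monotone missingness in y)
  for (seed in 43:46) {
    tab <- masked_table(200, 0.25, seed = seed)
    expect_equal(fit_em(tab)$r_hat, lawley_correct(tab)$r_hat,
      tolerance = 1e-4
    )
  }
})

test_that("the EM observed-data log-likelihood never decreases", {
  tab <- masked_table(300, 0.2, seed = 47)
  em <- fit_em(tab, report_loglik = TRUE)
  trace <- em$diagnostics$loglik_trace
  expect_gt(length(trace), 2)
  expect_true(all(diff(trace) > -1e-8))
})

test_that("EM is invariant to row order and affine predictor rescaling", {
  tab <- masked_table(250, 0.3, seed = 48)
  base <- fit_em(tab)$r_hat
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(fit_em(shuffled)$r_hat, base, tolerance = 1e-8)
  rescaled <- tab
  rescaled$x1 <- 3 * tab$x1 + 5
  rescaled$x2 <- -2 * tab$x2 + 1
  rescaled$z <- NULL
  expect_equal(fit_em(rescaled)$r_hat, base, tolerance = 1e-8)
})

test_that("EM reports non-convergence honestly", {
  tab <- masked_table(300, 0.2, seed = 49)
  expect_warning(em <- fit_em(tab, max_iterations = 3), "did not converge")
  expect_false(em$converged)
  expect_equal(em$iterations, 3L)
})

test_that("Lawley with identical predictor covariances is the identity", {
  tab <- masked_table(120, 0.5, seed = 50)
  desc_i <- describe_group(tab, "incumbents")
  # pretend the 'applicants' are the incumbents themselves
  est <- lawley_correct(desc_i, desc_i)
  expect_equal(est$r_hat, desc_i$corr["x1", "y"], tolerance = 1e-12)
})

test_that("Lawley reduces to univariate case A when x2 plays no role", {
  # incumbents: unit SDs, x2 uncorrelated with everything; applicants differ
  # from incumbents only in the SD of x1 (by the factor u)
  for (r in c(0.2, 0.45, 0.7)) {
    for (u in c(1.3, 2)) {
      desc_i <- make_desc("incumbents", 500,
        sds = c(x1 = 1, x2 = 1, y = 1), corr = corr3(0, r, 0)
      )
      desc_a <- make_desc("applicants", 500,
        sds = c(x1 = u, x2 = 1, y = NA), corr = corr3(0, NA, NA)
      )
      expect_equal(
        lawley_correct(desc_i, desc_a)$r_hat,
        correct_case_a(r, u)$r_hat
      )
    }
  }
})

test_that("multiple imputation approaches the ML estimate as m grows", {
  # the 0.01 agreement tolerance needs a sample large enough that the
  # between-imputation noise of a single m = 50 run sits well below it
  big <- masked_table(2000, 0.4, seed = 51)
  em_big <- fit_em(big)$r_hat
  mi50 <- fit_mice(big, m = 50, seed = 52)
  expect_equal(mi50$r_hat, em_big, tolerance = 0.01 / abs(em_big))
  expect_equal(length(mi50$diagnostics$estimates), 50)
  expect_gt(mi50$diagnostics$between_sd, 0)

  # mean absolute deviation from the ML estimate shrinks with m
  tab <- masked_table(400, 0.4, seed = 51)
  em <- fit_em(tab)$r_hat
  gap <- function(m) {
    mean(vapply(1:30, function(s) {
      abs(fit_mice(tab, m = m, iterations = 2, seed = 1000 + s)$r_hat - em)
    }, numeric(1)))
  }
  gaps <- c(gap(5), gap(20), gap(50))
  expect_true(all(diff(gaps) < 0))
})

test_that("imputation is reproducible from its seed and validates m", {
  tab <- masked_table(100, 0.5, seed = 53)
  expect_identical(
    fit_mice(tab, seed = 7)$r_hat,
    fit_mice(tab, seed = 7)$r_hat
  )
  expect_error(fit_mice(tab, m = 1), class = "valcorr_error_config")
})

test_that("estimators require a minimally informative incumbent group", {
  tiny <- data.frame(
    x1 = rnorm(10), x2 = rnorm(10),
    y = c(1, 2, rep(NA, 8))
  )
  expect_error(fit_em(tiny), "3 incumbents", class = "valcorr_error_data")
  expect_error(fit_mice(tiny), "3 incumbents", class = "valcorr_error_data")
})
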