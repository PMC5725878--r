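test_that("case A reduces correctly at its boundaries", {
  expect_equal(correct_case_a(0.37, 1)$r_hat, 0.37)
  expect_equal(correct_case_a(0, 5)$r_hat, 0)
  expect_equal(correct_case_a(0.5, 2)$r_hat, 1 / sqrt(1.75))
  expect_error(correct_case_a(0.5, 0), class = "valcorr_error_config")
})

test_that("case A applied to the published restricted statistics", {
  est <- correct_case_a(0.41, 1 / 0.67)
  expect_equal(round(est$r_hat, 2), 0.56)
})

test_that("case A is monotone in u and saturates at 1", {
  us <- c(1, 1.5, 2, 4, 10, 1e6)
  vals <- vapply(us, function(u) correct_case_a(0.3, u)$r_hat, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[length(vals)], 1, tolerance = 1e-6)
})

test_that("case C leaves the correlation unchanged when selection is inert", {
  expect_equal(correct_case_c(0.41, 0.5, 0.4, 1)$r_hat, 0.41)
  expect_equal(correct_case_c(0.41, 0, 0, 3)$r_hat, 0.41)
})

test_that("case C collapses to case A when the composite is the predictor", {
  set.seed(77)
  for (i in 1:50) {
    r <- runif(1, -0.95, 0.95)
    u <- runif(1, 0.5, 3)
    expect_equal(
      correct_case_c(r, 1, r, u)$r_hat,
      correct_case_a(r, u)$r_hat
    )
  }
})

test_that("both corrections map zero to zero and preserve sign", {
  expect_equal(correct_case_c(0, 0.5, 0, 2)$r_hat, 0)
  set.seed(78)
  for (i in 1:50) {
    r <- runif(1, 0.05, 0.9)
    rzx <- runif(1, 0, 0.9)
    rzy <- runif(1, 0, 0.9)
    u <- runif(1, 1, 3)
    expect_gt(correct_case_c(r, rzx, rzy, u)$r_hat, 0)
    expect_gt(correct_case_a(r, u)$r_hat, 0)
  }
})

test_that("case C recovers the applicant correlation on a large pool", {
  pool <- simulate_applicants(scenario_spec(200000), seed = 55)
  tab <- apply_selection(pool, selection_design(1, 1, 0.2))
  inc <- tab[tab$selected, ]
  est <- correct_case_c(
    cor(inc$x1, inc$y), cor(inc$z, inc$x1), cor(inc$z, inc$y),
    sd(tab$z) / sd(inc$z)
  )
  # reference: the unmasked applicant-pool correlation
  expect_equal(est$r_hat, cor(pool$x1, pool$y), tolerance = 0.01 / 0.6)
})

test_that("out-of-range corrected values are clamped with a warning", {
  expect_warning(
    est <- valcorr:::new_correction_estimate("case_a", 1.02),
    "clamped"
  )
  expect_equal(est$r_hat, 1)
})

test_that("disattenuation follows classical test theory", {
  expect_equal(disattenuate(0.4, 1), 0.4)
  expect_equal(disattenuate(0, 0.5), 0)
  expect_equal(disattenuate(0.59, 0.8), 0.59 / sqrt(0.8))
  expect_equal(round(disattenuate(0.59, 0.8), 2), 0.66)
  expect_error(disattenuate(0.95, 0.8), class = "valcorr_error_config")
})

test_that("the stepwise reliability chain reduces to case A without error", {
  rel1 <- reliability_spec(1, 1)
  for (r in c(0.2, 0.41, 0.7)) {
    for (u in c(1, 1.4925, 2.5)) {
      expect_equal(
        correct_hunter_schmidt(r, u, rel1)$r_hat,
        correct_case_a(r, u)$r_hat
      )
    }
  }
  # large u makes the implied incumbent reliability impossible
  expect_error(
    correct_hunter_schmidt(0.3, 2.5, reliability_spec(0.5, 0.7)),
    "inconsistent", class = "valcorr_error_config"
  )
})

test_that("the stepwise chain recovers a known true-score correlation", {
  # true scores with rho = 0.6; observed scores add independent error per
  # reliabilities 0.8 (predictor, applicants) and 0.7 (outcome); selection of
  # the top 20% on the predictor's true score (the selection model the chain
  # assumes)
  set.seed(90)
  n <- 100000
  rho <- 0.6
  tx <- rnorm(n, sd = sqrt(0.8))
  ty <- rho * sqrt(0.7 / 0.8) * tx + rnorm(n, sd = sqrt(0.7 * (1 - rho^2)))
  x <- tx + rnorm(n, sd = sqrt(0.2))
  y <- ty + rnorm(n, sd = sqrt(0.3))
  sel <- rank(-tx, ties.method = "first") <= 0.2 * n
  rel_y_inc <- 1 - 0.3 / var(y[sel])
  est <- correct_hunter_schmidt(
    cor(x[sel], y[sel]), sd(x) / sd(x[sel]),
    reliability_spec(0.8, rel_y_inc)
  )
  expect_equal(est$diagnostics$r_true_score, rho, tolerance = 0.02 / 0.6)
  expect_equal(est$r_hat, rho * sqrt(0.8), tolerance = 0.02 / 0.54)
})
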