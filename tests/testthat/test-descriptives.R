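toy_table <- function(x, y) {
  data.frame(x1 = x, x2 = seq_along(x), y = y, selected = rep(TRUE, length(x)))
}

test_that("describe_group computes textbook correlations", {
  expect_equal(describe_group(toy_table(1:3, c(1, 2, 3)))$corr["x1", "y"], 1)
  expect_equal(describe_group(toy_table(1:3, c(3, 2, 1)))$corr["x1", "y"], -1)
  # cov = 0.5 with unit SDs
  expect_equal(describe_group(toy_table(1:3, c(1, 3, 2)))$corr["x1", "y"], 0.5)
})

test_that("describe_group rejects tiny groups and flags degenerate columns", {
  expect_error(
    describe_group(toy_table(1:2, c(1, 2))),
    "at least 3", class = "valcorr_error_data"
  )
  const <- data.frame(x1 = c(1, 1, 1), x2 = 1:3, y = c(2, 1, 3))
  expect_warning(d <- describe_group(const), "Zero-variance")
  expect_true("x1" %in% d$degenerate)
  expect_true(is.na(d$corr["x1", "y"]))
  expect_equal(d$corr["x2", "y"], 0.5)
})

test_that("applicant-group outcome statistics use observed y only, flagged", {
  tab <- masked_table(200, 0.3, seed = 4)
  d <- describe_group(tab, "applicants")
  expect_false(d$y_complete)
  expect_equal(d$n_y_observed, sum(tab$selected))
  inc <- tab[tab$selected, ]
  expect_equal(d$corr["x1", "y"], cor(inc$x1, inc$y))
  # predictors use all rows
  expect_equal(d$corr["x1", "x2"], cor(tab$x1, tab$x2))
})

test_that("correlation matrices are symmetric, unit-diagonal and PSD", {
  for (seed in 1:5) {
    d <- describe_group(masked_table(100, 0.5, seed = seed), "incumbents")
    expect_equal(d$corr, t(d$corr))
    expect_equal(unname(diag(d$corr)), rep(1, 4))
    expect_gte(min(eigen(d$corr, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("u_ratio is 1 for a group against itself and warns when inverted", {
  tab <- masked_table(100, 0.5, seed = 2)
  d_a <- describe_group(tab, "applicants")
  d_i <- describe_group(tab, "incumbents")
  expect_identical(u_ratio(d_a, d_a, "x1"), 1)
  expect_gt(u_ratio(d_a, d_i, "x1"), 1)
  expect_warning(u <- u_ratio(d_i, d_a, "x1"), "< 1")
  expect_lt(u, 1)
})

test_that("u-ratios under truncation match closed-form truncated-normal moments", {
  # direct selection of the top 20% on x1 itself: u = 1/sqrt(variance ratio)
  tm <- truncation_moments(0.2)
  u_direct <- 1 / sqrt(tm$variance_ratio)
  expect_equal(u_direct, 2.139, tolerance = 1e-3)
  tab <- masked_table(200000, 0.2, seed = 8, weights = c(1, 0))
  u_hat <- sd(tab$x1) / sd(tab$x1[tab$selected])
  expect_equal(u_hat, u_direct, tolerance = 0.02)

  # compensatory selection on z = x1 + x2 (independent): the incumbent
  # variance of x1 decomposes as (Var(z | sel) + 2) / 4
  spec0 <- correlation_spec(0, 0, 0, 200000)
  tab2 <- apply_selection(
    simulate_applicants(spec0, seed = 9), selection_design(1, 1, 0.2)
  )
  sd_pred <- sqrt((2 * tm$variance_ratio + 2) / 4)
  expect_equal(sd(tab2$x1[tab2$selected]), sd_pred, tolerance = 0.01)
  expect_equal(sd(tab2$x1) / sd(tab2$x1[tab2$selected]), 1 / sd_pred,
    tolerance = 0.02
  )
})

test_that("semipartial correlation removes the suppression artifact", {
  expect_identical(semipartial_r(0.37, 0.5, 0), 0.37)
  # restricted statistics of a compensatory-selection cohort
  expect_equal(round(semipartial_r(0.37, -0.124, -0.71), 2), 0.40)
  expect_equal(round(semipartial_r(0.39, -0.06, -0.47), 2), 0.41)
  expect_equal(round(semipartial_r(-0.06, 0.39, -0.47), 2), 0.14)
  expect_error(semipartial_r(0.5, 0.5, 1), class = "valcorr_error_config")
})

test_that("semipartial stays in [-1, 1] over random valid triples", {
  set.seed(101)
  for (i in 1:200) {
    tr <- random_corr_triple()
    sp <- semipartial_r(tr["r_yx1"], tr["r_yx2"], tr["r_x1x2"])
    expect_lte(abs(sp), 1)
  }
})

test_that("beta weights relate to semipartials by the collinearity factor", {
  expect_equal(beta_weights(0.4, 0.1, 0), c(beta_x1 = 0.4, beta_x2 = 0.1))
  expect_equal(beta_weights(0.5, 0.5, -0.5),
    c(beta_x1 = 1, beta_x2 = 1))
  set.seed(202)
  for (i in 1:50) {
    tr <- random_corr_triple()
    b <- beta_weights(tr["r_yx1"], tr["r_yx2"], tr["r_x1x2"])
    sp <- semipartial_r(tr["r_yx1"], tr["r_yx2"], tr["r_x1x2"])
    expect_equal(unname(b["beta_x1"]), sp / sqrt(1 - tr["r_x1x2"]^2),
      ignore_attr = TRUE
    )
  }
})

test_that("residualize matches hand arithmetic and its invariants", {
  # slope 2, intercept 2 after one +5 perturbation: residuals known exactly
  fix <- data.frame(
    x1 = c(3, 5, 12, 9, 11), x2 = 1:5, y = rep(1, 5),
    selected = rep(TRUE, 5)
  )
  res <- residualize(fix, group = "incumbents")
  expect_equal(res$.resid, c(-1, -1, 4, -1, -1))

  # target == covariate: all residuals zero
  same <- data.frame(x1 = 1:5, x2 = 1:5, y = rep(1, 5), selected = TRUE)
  expect_equal(residualize(same)$.resid, rep(0, 5))

  # in-sample orthogonal covariate: slope 0, residual SD = target SD
  orth <- data.frame(
    x1 = c(1, 2, 3, 4), x2 = c(1, -1, -1, 1), y = 1, selected = TRUE
  )
  expect_equal(sd(residualize(orth)$.resid), sd(orth$x1))

  # zero correlation with the covariate within the fitting group
  tab <- masked_table(300, 0.4, seed = 6)
  r <- residualize(tab, group = "incumbents")
  expect_lt(abs(cor(r$.resid, r$x2)), 1e-10)
  expect_lt(abs(mean(r$.resid)), 1e-10)

  expect_error(
    residualize(same, target = "x2", covariate = "y"),
    "constant", class = "valcorr_error_data"
  )
})
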