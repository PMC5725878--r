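# Shared fixtures, all generated in code.

scenario_spec <- function(n = 1000) correlation_spec(0.60, 0.20, 0.00, n)

# simulate, select the top fraction on x1 + x2, mask rejected outcomes
masked_table <- function(n, rate, spec = scenario_spec(n), seed = 1,
                         weights = c(1, 1)) {
  spec$n_applicants <- as.integer(n)
  apply_selection(
    simulate_applicants(spec, seed = seed),
    selection_design(weights[1], weights[2], rate)
  )
}

# hand-built group_descriptives for algebraic identities
make_desc <- function(group, n, sds, corr,
                      means = setNames(rep(0, length(sds)), names(sds))) {
  structure(
    list(
      group = group, n = n, n_y_observed = n, y_complete = TRUE,
      means = means, sds = sds, corr = corr, degenerate = character(0)
    ),
    class = "group_descriptives"
  )
}

corr3 <- function(r_x1x2, r_yx1, r_yx2) {
  matrix(
    c(1, r_x1x2, r_yx1, r_x1x2, 1, r_yx2, r_yx1, r_yx2, 1),
    3, 3,
    dimnames = list(c("x1", "x2", "y"), c("x1", "x2", "y"))
  )
}

# random valid correlation triple (guaranteed PSD: sample correlations of
# random data)
random_corr_triple <- function(n = 20) {
  R <- cor(matrix(rnorm(3 * n), ncol = 3))
  c(r_yx1 = R[1, 3], r_yx2 = R[2, 3], r_x1x2 = R[1, 2])
}
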