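# valcorr

Corrected predictive-validity estimation for selection tests under
compensatory selection and range restriction.

## The problem

Admission and personnel-selection tests are validated by correlating test
scores with a later outcome (first-year grades, job performance), but the
outcome exists only for the people who were admitted — and admission
depended on the test. The incumbent correlation `r(y, x1 | incumbents)`
is therefore a biased, usually badly attenuated, estimate of the
correlation in the full applicant pool, which is the quantity a selection
policy actually cares about.

The situation is worse under **compensatory selection**: admission by a
weighted composite `Z = w1·X1 + w2·X2` (for example a test score and a
school GPA). Truncating the pool on `Z` induces a *negative* correlation
between the two predictors among those admitted even when they are
independent among applicants, making each predictor a suppressor for the
other, and makes the restriction *indirect* — selection acted on `Z`, not
on `X1` — so the textbook direct-restriction correction is applied to
data that violate its assumptions.

valcorr is aimed at psychometricians, admission researchers and
methodologists who need to (a) correct an observed validity coefficient
properly and (b) see, by simulation, how badly the wrong correction
misleads.

## Methods

Applicants are modelled as trivariate normal `(X1, X2, Y)` with a known
selection rule (top fraction on `Z`); outcomes of rejected applicants are
missing at random by construction. Four corrections are implemented:

- **Thorndike case A** (direct restriction):
  `r̂ = u·r / sqrt(1 − r² + u²r²)` with `u = s(x1|applicants)/s(x1|incumbents)`.
- **Thorndike case C** (indirect restriction on the composite `z`,
  `k = u_z² − 1`):
  `r̂ = (r_yx1 + r_zx1·r_zy·k) / sqrt((1 + r_zx1²k)(1 + r_zy²k))`.
- **EM**: maximum-likelihood estimation of the trivariate normal from the
  incomplete table, with the Pearson–Lawley closed form kept as an
  internal cross-check.
- **MICE**: proper Bayesian multiple imputation of the missing outcomes,
  pooling the per-imputation correlations by their arithmetic mean.

A Hunter–Schmidt stepwise chain (range restriction plus
reliability-based disattenuation to operational validity) is also
provided. A Monte Carlo harness (`run_validity_study()`) scores all
methods by bias, RMSE and percentile intervals across selection rates.
See the methods vignette (`vignettes/range-restriction-methods.Rmd`) for
assumptions, defaults and design choices.

## Worked example

Simulate a cohort shaped like a medical-school intake — 714 applicants,
29 % admitted on test-score-minus-GPA (GPA on a reversed scale, so its
weight is negative) — and correct the incumbent validity:

```r
library(valcorr)

spec <- correlation_spec(rho_yx1 = 0.50, rho_yx2 = -0.25,
                         rho_x1x2 = -0.10, n_applicants = 714)
cohort <- simulate_applicants(spec, seed = 42) |>
  apply_selection(selection_design(weight_x1 = 1, weight_x2 = -1,
                                   selection_rate = 0.29))
validity_report(cohort, weights = c(1, -1), seed = 42)
```

```
<validity_report: 714 applicants, 208 incumbents>
u(x1) = 1.232, u(z) = 1.989

Suppression / restriction decomposition:
            step                             description     r
     first_order           incumbent correlation r_yx1|i 0.406
     semipartial          suppression removed: r_yx1.2|i 0.381
 range_corrected indirect-restriction corrected (case_c) 0.560

Corrected validity estimates:
 method r_hat u_used iterations converged
 case_a 0.453   1.23         NA        NA
 case_c 0.560   1.99         NA        NA
     em 0.543     NA        483      TRUE
   mice 0.531     NA         10      TRUE
```

Reading: the raw incumbent correlation (0.406) is far below the
population validity (0.50) that generated the data. The three
indirect-restriction methods (case C, EM, MICE) cluster around the right
answer; case A, whose direct-selection assumption this design violates,
stays visibly too low. `u(x1)` and `u(z)` are the
applicant-to-incumbent SD ratios the formula-based corrections consumed.

The same comparison at scale:

```r
run_validity_study(correlation_spec(0.60, 0.20, 0.00, 1000),
                   rates = c(0.3, 0.2, 0.1), n_reps = 100, seed = 1)
```

```
<validity_study: 100 reps x rates {0.3, 0.2, 0.1}, reference = realized>
 method rate n_reps     mean     sd   rmse  ci_low ci_high n_failed
 case_a  0.3    100 -0.07566 0.0418 0.0864 -0.1512 0.00304        0
 case_a  0.2    100 -0.08275 0.0571 0.1004 -0.2143 0.02093        0
 case_a  0.1    100 -0.13667 0.1060 0.1726 -0.3735 0.05508        0
 case_c  0.3    100 -0.00793 0.0444 0.0449 -0.0864 0.06562        0
 case_c  0.2    100  0.01023 0.0504 0.0512 -0.0896 0.10343        0
 case_c  0.1    100 -0.02686 0.1088 0.1115 -0.2712 0.14134        0
     em  0.3    100 -0.00530 0.0364 0.0366 -0.0705 0.05364        0
     em  0.2    100  0.01242 0.0473 0.0486 -0.1009 0.10230        0
     em  0.1    100 -0.01962 0.1020 0.1033 -0.2666 0.13029        0
   mice  0.3    100 -0.00992 0.0370 0.0381 -0.0767 0.05449        0
   mice  0.2    100  0.00386 0.0488 0.0487 -0.1111 0.10022        0
   mice  0.1    100 -0.04428 0.1087 0.1168 -0.3138 0.11803        0
```

`mean` is the bias against each replication's realized applicant
correlation: case A's bias grows sharply as selection tightens, while the
indirect methods stay near zero; EM is the most precise. `tidy()`,
`glance()` and `autoplot()` methods are available on both result types.

A command-line interface wraps the same workflow
(`Rscript inst/cli/valcorr.R simulate|correct|montecarlo ...`, YAML/JSON
configs, metadata headers and distinct exit codes for config vs data
errors); see `?cli_main`.

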