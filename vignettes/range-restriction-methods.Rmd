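---
title: "Correcting predictive validity for compensatory selection and range restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting predictive validity for compensatory selection and range restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valcorr)
```

## The problem

A selection test is validated by correlating test scores with a later
outcome — but the outcome is only observed for the people who were
admitted. When admission itself depended on the test (directly, or through
a composite that includes it), the incumbent correlation $r_{yx_1|i}$ is a
biased, usually severely attenuated, estimate of the applicant-pool
validity $r_{yx_1|a}$. valcorr implements and compares the standard
families of corrections for this situation, with particular attention to
*compensatory* selection: admission by a weighted sum of two predictors,

$$Z = w_1 X_1 + w_2 X_2,$$

which induces a negative correlation between the predictors among those
admitted even when they are independent in the applicant pool.

## The model

Applicants are modelled as draws from a trivariate normal
$(X_1, X_2, Y) \sim N(0, \Sigma)$ with unit variances, so $\Sigma$ is the
correlation matrix $(\rho_{yx_1}, \rho_{yx_2}, \rho_{x_1x_2})$ declared in
a `correlation_spec()`. A `selection_design()` admits the top fraction
$p$ on $Z$; the outcome of every rejected applicant is set to missing.
Because rejection is a deterministic function of the fully observed
predictors, the missingness is *missing at random* (MAR) in Rubin's sense,
and the missingness pattern is monotone: $y$ is the only incomplete
column.

Truncating the pool on $Z$ has closed-form consequences
(`truncation_moments()`): with cut point $c = \Phi^{-1}(1-p)$ and hazard
$\lambda = \phi(c)/p$, the selected composite has mean shift $\lambda$ and
variance ratio $1 - \lambda(\lambda - c)$. For equal weights and
independent unit-variance predictors,
$\mathrm{Var}(X_1 \mid \text{sel}) = (\mathrm{Var}(Z \mid \text{sel}) + 2)/4$
and
$\mathrm{Cov}(X_1, X_2 \mid \text{sel}) = (\mathrm{Var}(Z \mid \text{sel}) - 2)/4$,
which at a 20 % admission rate gives an incumbent predictor correlation
near $-0.64$ — the selection-geometry oracle the test suite checks by
simulation at $n = 200{,}000$.

## Suppression decomposition

Among incumbents, the induced negative $r_{x_1x_2|i}$ makes each predictor
a *suppressor* for the other. `validity_report()` therefore reports a
three-step decomposition: the first-order incumbent correlation
$r_{yx_1|i}$; the semipartial correlation

$$r_{y(x_1 \cdot x_2)} = \frac{r_{yx_1} - r_{yx_2}\, r_{x_1x_2}}
  {\sqrt{1 - r_{x_1x_2}^2}},$$

which removes the suppression; and the range-restriction-corrected value
from the best available indirect-selection method.

## The four correction methods

**Thorndike case A** (`correct_case_a()`) assumes selection was direct on
$x_1$ itself:

$$\hat r = \frac{u\, r}{\sqrt{1 - r^2 + u^2 r^2}},
  \qquad u = \frac{s_{x_1|a}}{s_{x_1|i}}.$$

Under compensatory selection its assumptions are violated, and it
underestimates validity by an amount that grows as selection tightens —
that ordering is asserted by the Monte Carlo tests. Inside the harness,
case A consumes the incumbent semipartial correlation together with the
raw predictor u-ratio; a variant that also uses the residualized
predictor's u-ratio is available via `case_a_u = "residual"` and is close
to unbiased in this design, but the raw-u recipe is the default because it
is the behaviour of the classical formula as analysts typically apply it
to a single predictor's standard deviations.

**Thorndike case C** (`correct_case_c()`) models selection as *indirect*,
on a third variable $z$ observed in both groups (here, the admission
composite). With $k = u_z^2 - 1$:

$$\hat r_{yx_1} = \frac{r_{yx_1} + r_{zx_1} r_{zy}\, k}
  {\sqrt{\left(1 + r_{zx_1}^2 k\right)\left(1 + r_{zy}^2 k\right)}}.$$

When the composite *is* the predictor ($r_{zx_1} = 1$, $r_{zy} = r$) this
collapses to case A — a property test.

**EM** (`fit_em()`) treats the masked table as an incomplete trivariate
normal sample and iterates expectation and maximization to the maximum
likelihood estimate of $\Sigma$, reading off $\hat r_{yx_1}$. Because only
$y$ is missing, the E-step has a closed form: the conditional mean and
variance of $y$ given $(x_1, x_2)$ under the current parameters. The
implementation precomputes the cross-product statistics of the complete
and incomplete row blocks once, so each iteration is $O(1)$ regardless of
sample size. For monotone normal missingness the ML solution is also
available in closed form via the Pearson–Lawley formulas
(`lawley_correct()`): regression slopes fitted among incumbents are
propagated through the applicant predictor covariance. The package keeps
both routes and tests that they agree to $10^{-4}$; the closed form uses
maximum-likelihood ($1/n$) covariance scaling throughout, because the
fixed point of EM is not invariant to mixing $1/n$ and $1/(n-1)$
conventions between the two groups.

**MICE** (`fit_mice()`) is multiple imputation by chained equations. With
only one incomplete column the chained loop degenerates to repeated draws
of a single conditional model, which the implementation notes in its
diagnostics. Imputation is *proper* Bayesian linear regression of $y$ on
$(x_1, x_2)$, fitted on the observed-outcome rows: each sweep redraws the
residual variance from its scaled inverse-$\chi^2$ posterior, the
coefficients from their conditional normal posterior, and the missing
outcomes from the posterior predictive. Each of the $m$ completed tables
yields a $\mathrm{cor}(x_1, y)$; the pooled estimate is their arithmetic
mean (Fisher-$z$ pooling via `pool = "fisher_z"`).

**Hunter–Schmidt stepwise chain** (`correct_hunter_schmidt()`) combines
range-restriction correction with classical-test-theory disattenuation to
an *operational validity*: correct for criterion unreliability among
incumbents, convert the applicant predictor reliability to the incumbent
group via $\rho_{xx|i} = 1 - (1 - \rho_{xx|a})u_x^2$, correct for
predictor unreliability, apply case A on the true-score u-ratio
$u_T = u_x \sqrt{\rho_{xx|a}/\rho_{xx|i}}$, and re-attenuate by
$\sqrt{\rho_{xx|a}}$. The chain's step composition is not standardized in
the literature; the implemented order is the one the recovery test
validates on synthetic true scores with known reliabilities. An impossible
implied incumbent reliability (large $u$ with low applicant reliability)
raises a configuration error rather than a silent NaN.

## Monte Carlo harness

`run_validity_study()` repeats generate → select → correct and scores each
method by its error $\hat r - r_{\text{ref}}$.

- **Error reference.** By default the reference is each replication's
  *realized* applicant correlation, not the population $\rho$: the
  corrected estimate can at best recover what that pool's data contain.
  `error_reference = "population"` is available.
- **Summaries.** `mean` (bias), `sd`, `rmse` (includes the bias,
  $\mathrm{rmse}^2 = \mathrm{mean}^2 + \tfrac{n-1}{n}\mathrm{sd}^2$ — an
  exact identity in the tests), and empirical 2.5/97.5 percentile
  intervals. Percentiles are used rather than normal-theory
  $\pm 1.96\,\mathrm{sd}$ because the error distributions are visibly
  skewed at strict selection rates.
- **Seeds.** One top-level seed; per-replication child seeds come from
  `split_seed()` (seed the generator once, draw `sample.int(2^31 - 2, n)`),
  so any single replication is reproducible in isolation.
- **Failures.** A replication that errors is counted in `n_failed` and
  warned about, never silently dropped.

## Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| `mice_m` | 20 | pooled-estimate Monte Carlo noise $\approx$ between-SD$/\sqrt{m}$; 20 puts it near 0.005 at cohort sizes of a few hundred incumbents |
| `mice_iterations` | 10 | burn-in sweeps of the (degenerate) chained loop; convergence is immediate with one incomplete column, 10 is conservative |
| `em_tolerance` | 1e-8 | maximum absolute change in means, SDs and correlations between iterations; far below any reported digit |
| `em_max_iterations` | 5000 | EM's linear convergence slows as the missing fraction grows; 5000 covers 90 % missingness, and hitting the cap sets `converged = FALSE` with a warning |
| `selection_rate` | — | fraction admitted, in (0, 1); the number admitted is `ceiling(rate * n)` with stable ties (first occurrence wins) |
| `error_reference` | "realized" | see above |
| `case_a_u` | "raw" | see above; "residual" available |
| pooling | "mean" | arithmetic mean of correlations; `"fisher_z"` available |

The u-ratio helper always returns $s_a/s_i$ and warns — rather than
auto-inverting — when it is below 1, since a published ratio may be
printed on either scale; `validity_report(invert_u = TRUE)` flips it
explicitly.

## Numerical and degenerate-input choices

- Corrected correlations outside $[-1, 1]$ are clamped with a warning,
  never silently.
- Specs are validated for positive semidefiniteness (smallest eigenvalue
  $\ge -10^{-10}$).
- Zero-variance columns produce flagged `NA` correlations with a warning,
  not zeros.
- Fewer than 3 incumbents, or a complete outcome column with no declared
  selection split ("nothing to correct"), raise classed errors
  (`valcorr_error_data` / `valcorr_error_config`) that the CLI maps to
  exit codes 3 and 2.
- With a complete table, `fit_em()` and `fit_mice()` return the sample
  correlation exactly (one "iteration", zero between-imputation spread).

## What the generator does and does not emulate

`simulate_applicants()` draws exact multivariate normal pools
(`exact_moments = TRUE` forces the sample moments to match the spec, for
debugging). It emulates the joint structure that drives the selection
artefacts — compensatory truncation, induced suppression, MAR
missingness — and supports negative weights so reversed scales (grading
systems where 1 is best) can be mimicked. It does **not** emulate
non-normal score distributions, ceiling effects, self-selection of
applicants, measurement error (except through the explicit
reliability-based chain), or selection on variables outside the model.
Passing tests therefore demonstrate correctness *under the model*, not
robustness to real admission data that violate it.

## Problem sizes used by the test suite

The packaged tests run a 300-replication study at pool size 1000 over
admission rates 30/20/10 % (about three minutes), oracle equivalences at
$n = 2000$ (chosen so the between-imputation noise of a single $m = 50$
run sits well below the 0.01 agreement tolerance), and selection-geometry
checks at $n = 200{,}000$. These sizes are the package's own trade-off
between statistical resolution and a test suite that runs in minutes;
nothing prevents users from running `run_validity_study()` at
`n_reps = 1000` or more.

## Known limitations

- Exactly two predictors and one outcome; no general missing-data
  patterns (predictors must be complete).
- Corrections address selection-induced restriction only; unmodelled
  measurement error outside `correct_hunter_schmidt()` is untouched.
- Rubin's rules for the *variance* of the pooled MICE estimate are not
  implemented — pooling is of point estimates only.
- The Hunter–Schmidt chain's step order follows one defensible reading of
  the stepwise procedure; published operational-validity numbers computed
  with a different composition will differ.
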