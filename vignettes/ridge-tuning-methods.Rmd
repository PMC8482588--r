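---
title: "Tuning ridge logistic regression in small or sparse data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning ridge logistic regression in small or sparse data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgetune)
```

## The problem

Logistic regression with a binary outcome $y_i \in \{0,1\}$ and covariates
$x_i \in \mathbb{R}^K$ models
$\pi_i = P(Y=1\mid x_i) = \operatorname{expit}(\beta_0 + x_i'\beta)$.
In small samples, with rare events, or when some covariate configuration
perfectly predicts the outcome (*separation*), maximum likelihood (ML)
estimates are biased away from zero, unstable, or infinite.  Two families of
remedies are implemented here:

* **Firth's correction**: maximize $\ell(\beta) + \tfrac12 \log |I(\beta)|$,
  the likelihood penalized by Jeffreys' invariant prior.  Estimates are
  always finite and first-order unbiased, but because the intercept sits in
  the penalty the average predicted probability is pulled towards one half.
  **FLIC** (Firth logistic regression with intercept correction) keeps the
  Firth slopes and re-estimates the intercept by one-dimensional ML with the
  slope part as an offset, which forces the mean predicted probability to
  equal the observed event rate exactly (it is the intercept's ML score
  equation).
* **Ridge logistic regression**: maximize
  $\ell(\beta) - \tfrac{\lambda}{2}\sum_{k=1}^K \beta_k^2$ on standardized
  covariates, with the intercept unpenalized.  The complexity parameter
  $\lambda$ is either *tuned* from the data or *fixed in advance* from prior
  assumptions about plausible effect sizes.

The package's central question is empirical: in small or sparse datasets,
does tuning $\lambda$ help or hurt, compared with a fixed, prior-based
penalty or with Firth/FLIC?  Everything needed to study that question is
included: the estimators, the tuning criteria, oracle benchmarks, a
synthetic data generator emulating a realistic prognostic-study covariate
structure, and calibration-focused performance measures.

## Estimation

All penalized fits use damped Newton–Raphson with step-halving on the
objective.  Convergence requires both the maximal absolute score and the
maximal coefficient change to fall below $10^{-8}$, within 100 iterations.
Under separation the unpenalized likelihood has no maximizer; `fit_ml()`
then freezes coefficients at $\pm 50$ and reports `converged = FALSE`
instead of failing, which keeps simulation loops alive while making the
divergence visible.  For $\lambda > 0$ the ridge objective is strictly
concave, so the optimizer's result is the unique maximizer; a property test
confirms that different starting values agree to $10^{-6}$.

Ridge fits are computed on standardized covariates (mean 0, sd 1, sample sd
with the $N-1$ denominator; the denominator choice is conventional and
matters only in the third decimal at these sample sizes).  Every
standardized-scale fit also carries the back-transformed original-scale
view ($\beta_k^{orig} = \beta_k^{std}/s_k$, intercept shifted accordingly);
predictions from either view are identical to numerical precision.
Coefficient tables and the coefficient-error measures in this package use
the original-scale view, which is the convention under which all the fixture
coefficient values reproduce; the standardized view is what the penalty and
the prior interpretation act on.

### Ridge by data augmentation

`fit_ridge_augmented()` implements the prior-as-pseudo-data device: for
each covariate two artificial records with value $1/s$ in that covariate
(zero elsewhere, no intercept contribution), one with outcome 1 and one
with outcome 0, each weighted $2 s^2 \lambda$.  A second-order expansion of
the pseudo-records' likelihood at $\beta = 0$ gives exactly the ridge
penalty $-\lambda \beta_k^2/2$, so weighted ML on the augmented data
approximates the penalized fit, with error vanishing as $s$ grows.  The
outcome/intercept handling of the pseudo-records (one event and one
non-event, intercept column zeroed) makes the pseudo-score vanish at zero
and leaves the intercept unpenalized.  The defaults use $s=10$; tests
verify agreement with the exact optimizer to $10^{-2}$ and monotone
improvement over $s \in \{5, 10, 50\}$.  The direct Newton optimizer, being
exact and cheaper, is the workhorse everywhere else (tuning, simulation);
the augmentation is provided both as the classical computational route and
as a cross-check.

### Separation detection

`detect_separation()` solves a small linear program: maximize the sum of
signed margins $(2y_i - 1) \tilde{x}_i'b$ subject to all margins
nonnegative and a unit box on $b$.  The data admit a separating (possibly
degenerate) hyperplane — equivalently, some ML coefficient is infinite —
exactly when the optimum is positive.  This detects quasi-complete as well
as complete separation.  All constraints are written as inequalities
feasible at $b=0$ so the solver needs no phase-1 step; duplicated
covariate-outcome rows are collapsed first.  A brute-force two-covariate
oracle (enumeration of the boundary rays of the feasibility cone) confirms
the LP on random small instances.

## Tuning criteria

All criteria are evaluated over a fixed grid of 200 log-linearly
equidistant $\lambda$ values from $10^{-6}$ to $100$ (`make_grid()`).

* **D** — leave-one-out cross-validated deviance
  $-2\sum_i \{y_i \log \hat\pi_{(-i)} + (1-y_i)\log(1-\hat\pi_{(-i)})\}$.
* **GCV** — $N \cdot D/(N - df_e)^2$ with $df_e$ the effective degrees of
  freedom, $\operatorname{trace}(A (A + P)^{-1})$, where $A$ is the
  unpenalized Fisher information at the penalized estimate and $P$ the
  penalty matrix; $df_e$ runs from $K+1$ at $\lambda = 0$ down to 1 (the
  free intercept) as $\lambda \to \infty$.
* **CE** — leave-one-out classification error at a cut-off $c$, ties counted
  one half.  With unbalanced outcomes $c = 1/2$ would send almost everything
  to the majority class, so the default cut-off is the observed event rate.
* **RCV50 / RCV95** — deviance by 10-fold cross-validation repeated 50
  times; the tuned value is the median (or 95% quantile) of the
  per-repetition minimizers, snapped to the nearest grid value on the log
  scale.
* **AIC** — $-2\ell(\hat\beta) + 2 df_e$, with the *unpenalized*
  log-likelihood at the penalized estimate.

Design choices the criteria definitions leave open, and how they are
resolved here:

* Leave-one-out refits reuse the full-data standardization (covariates are
  standardized once per dataset); re-standardizing inside each fold would
  change the parameter being penalized from fold to fold.
* Rows with identical covariate pattern *and* outcome are collapsed into
  weighted fits before leave-one-out; this changes nothing (a weighted
  equivalence test asserts identity to $10^{-8}$) but reduces the LOOCV
  cost from $N$ refits to one per distinct pattern — on the 2×2 fixture
  datasets, 3 or 4 refits instead of 100 per grid point.  Fits along the
  grid and across left-out patterns are warm-started.
* Ties: D, GCV and AIC break towards the smaller $\lambda$ (first minimum
  scanning the ascending grid).  CE is discrete with no unique optimum; the
  *largest* $\lambda$ minimizing CE is selected.
* CE uses leave-one-out predictions like D; the 10-fold machinery is used
  only by RCV, which is defined for the deviance.
* Repeated-CV folds are drawn without outcome stratification; a repetition
  whose folds leave a single-class training set is redrawn (and counted).
  The quantile over repetitions uses the standard interpolating definition
  (R type 7) before snapping to the grid.

### Fixed, prior-based penalties

Ridge estimation is Bayesian posterior-mode estimation under independent
$N(0, v_{prior})$ priors on the standardized coefficients, with
$\lambda = 1/v_{prior}$.  `prior_to_lambda()` converts a symmetric
$(1/u,\, u)$ prior odds-ratio interval at level $1-\alpha$ for a
standardized covariate into $v_{prior} = (\log u / z_{1-\alpha/2})^2$.
Following the convention of round prior variances, $v_{prior}$ is rounded
to two significant digits before inversion, so $u = 4$ gives
$v_{prior} = 1/2$, $\lambda = 2$ (the *informative prior*, IP) and $u = 16$
gives $\lambda = 1/2$ (the *weakly informative prior*, WP).

### Oracles

Two benchmarks use the unknown truth to pick $\lambda$ by exhaustive grid
scan: the explanation oracle (OEX) minimizes $(\hat\beta_1 - \beta_1)^2$
and the prediction oracle (OP) minimizes $\sum_i (\hat\pi_i - \pi_i)^2$.
Whether OEX should compare coefficients on the standardized or the original
scale is not determined by the definition; here the standardized scale is
used (the ridge path lives there), with the true standardized coefficient
obtained from the generating distribution's covariate standard deviation.

## The synthetic data generator

The generator emulates a low-dimensional biomedical prognostic study.
Fifteen covariates arise as transformations of a correlated standard normal
vector $Z$: four binary threshold indicators ($X_1$–$X_4$, prevalences 0.80,
0.36, 0.50, 0.50), two three-level ordinal double indicators ($X_5$, $X_6$)
and nine continuous variables built from affine-floor, shifted-exponential
and shifted-square maps ($X_7$–$X_{15}$).  The floor bracket is applied as
truncation towards zero.  Covariates $X_{11}$–$X_{15}$ never enter the
outcome model; scenarios with `noise = TRUE` add them to the analysis set
as pure noise.

Two specification details required a decision:

* **The pairwise-correlation table is, taken literally, indefinite** (its
  minimum eigenvalue is about $-0.075$), so no multivariate normal has
  exactly these correlations.  The sampler uses the nearest positive
  definite correlation matrix in the Frobenius sense (Higham alternating
  projections via `Matrix::nearPD`); no entry moves by more than 0.023.
  `correlation_matrix(adjusted = FALSE)` exposes the raw specification.
* **Truncation.**  Continuous covariates are drawn from truncated
  distributions, bounded at the third quartile plus five times the
  interquartile range of the underlying distribution.  Applying that rule
  on the transformed scale would truncate up to 1.3% of draws of the
  heavy-tailed log-normal covariates and visibly shift their means and
  standard deviations away from the schema's stated values (e.g. the mean
  of $X_8$ from 146 to about 128); applying it to the *latent normal* scale
  ($z^* \approx 7.42$) leaves all stated moments intact while still
  guarding against pathological extremes.  The latent-scale reading is used,
  implemented by conditional redraw of the offending latent coordinate given
  the others (a conditional univariate normal), so the joint law of the
  remaining coordinates is untouched.  The induced transformed-scale
  thresholds, together with the marginal sds and sextile quantiles of the
  continuous covariates, are frozen from a seeded $10^6$-draw reference
  sample into `inst/extdata/simulation_reference.json`
  (regenerable with `scripts/freeze_reference.R`).

True coefficients: fixed log odds ratios 2.08, 1.39, 0.69, 0.69, 0.35, 0.35
for $X_1$–$X_6$; for $X_7$–$X_{10}$ the coefficient making the log odds
ratio between the first and fifth sextile of the covariate's distribution
equal to 0.69 (about 0.036, 0.0031, 0.0038, 0.036) — computed from the
frozen sextiles rather than hard-coded, so the standardized views
($\beta_k \cdot sd_k$) come out consistent.  An effect multiplier
$a \in \{0.5, 1\}$ scales all coefficients.  The intercept is calibrated by
bisection (to $10^{-6}$) so that the mean of
$\operatorname{expit}(\beta_0 + a\, x'\beta)$ over a large covariate
reference sample equals the target marginal event rate (0.1 or 0.25); the
reference sample can be shared across scenarios to avoid spurious
between-scenario Monte-Carlo differences.

The factorial design crosses $N \in \{100, 250, 500\}$, $K \in \{2,5,10\}$,
$a \in \{0.5, 1\}$, event rate $\in \{0.1, 0.25\}$ and noise
(absent/present): 72 scenarios, extended to 88 with $N = 1000$ for
$K \in \{5, 10\}$.

The single-covariate illustration sampler draws $x \sim \text{Bernoulli}(0.8)$
and $y$ from $\operatorname{expit}(-3.05 + x)$ — marginal event rate 0.10,
true slope 1 — and the two printed 2×2 fixture datasets (one
quasi-separated, one kept from separation by a single event) are available
as `illustration_dataset(1)` and `illustration_dataset(2)`.

### What the generator does and does not emulate

It reproduces mixed covariate types, skewed and heavy-tailed marginals, a
realistic correlation structure, rare outcomes, and the resulting high
prevalence of separation (a majority of replicates in the sparsest
scenarios).  It does not emulate missing data, measurement error,
model misspecification (outcomes are generated from the logistic model
itself), or covariate structures other than the fixed schema.  Passing
tests therefore certify the estimators and the tuning behaviour under a
realistic-but-correct generating model, not robustness to
misspecification.

## Performance evaluation

Per scenario, a validation set of 10,000 observations with freshly drawn
outcomes is generated once.  Per replicate and method the package records
the tuned $\lambda^*$ (with a boundary flag), $\hat\beta_1$ on both scales,
a separation flag, the calibration slope, the c-index on the validation
outcomes and the summed squared prediction error against the true
probabilities.  Aggregation gives RMSE of $\hat\beta_1$, pooled RMSE of
predictions, slope quartiles, RMSD of log slopes
($\sqrt{\text{mean}(\log^2 \text{slope})}$, slopes winsorized at 0.01 so
rare nonpositive slopes stay finite), MAD of log slopes (same floor — the
log is undefined otherwise, and a median-based measure barely notices it;
quantile summaries of the slopes themselves use the raw values), mean
c-index, the MAD of
$\log_{10}\lambda^*$ and the Spearman correlation between slopes and tuned
$\lambda^*$.  The MAD uses the conventional normal-consistency factor
1.4826 by default; because that convention is not universal, the raw MAD
is emitted alongside.  The calibration slope is the plain ML logistic
coefficient of validation outcomes on the fitted linear predictor; a
numerically constant linear predictor is reported as slope 0 with a
degeneracy flag rather than dropped silently.  Method-level failures
(e.g. FLIC on an all-non-event replicate) are recorded per replicate and
excluded pairwise, with counts.

## Reproducibility and problem sizes

All experiment randomness flows from one root seed through deterministic
child seeds per (scenario, replicate), so replicate $r$ can be regenerated
in isolation and an interrupted `run_experiment()` resumed from its
per-scenario checkpoint files yields byte-identical outputs.

The full factorial study (88 scenarios × 1000 replicates with LOOCV over a
200-point grid) is a cluster-scale computation.  The package's tests and
its acceptance script work at desk scale by design: the illustration
mini-study at its native 500 replicates (pattern-collapsed LOOCV makes
this about a minute and a half), oracle-dominance and slope-variability
checks on a 50-replicate sparse scenario, the tuned-versus-oracle
anti-correlation on 200 replicates, and determinism/resume checks on a
2-scenario × 20-replicate plan with a 50-point grid.  Monte-Carlo
tolerances in the tests correspond to these sizes.

## Known limitations

* No confidence intervals or hypothesis tests for the penalized fits; the
  package targets point estimation and prediction accuracy.
* The Jeffreys-prior fit degrades when the Fisher information is nearly
  singular (highly collinear covariates); ridge is preferable there.
* `fit_ridge_direct` refuses genuinely non-converged penalized fits rather
  than returning a capped estimate; inside leave-one-out loops a capped
  intercept-divergent fit (single-class training data) is used with its
  finite clamped predictions, which is the behaviour the deviance needs.
* The prior-based penalties assume a common prior variance for all
  standardized coefficients; per-coefficient penalties are not implemented.
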