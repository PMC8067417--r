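---
title: "Fiducial, frequentist, and Bayesian inference for random-intercept models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial, frequentist, and Bayesian inference for random-intercept models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

The package analyzes long-format repeated-measures data — the motivating
application is per-tertile systolic blood-pressure responsivity (SBP-R,
task SBP minus resting baseline, in mmHg) observed up to 24 times per
person (2 waves × 12 tertiles of time-on-task) — with a two-level linear
mixed model.  At level 1, within person $i$ at occasion $t$,

$$y_{ti} = \beta_{0i} + \beta_{1i}\,\mathrm{Tertile}_{ti} + r_{ti},$$

and at level 2 the person-specific intercepts and slopes are linear in
person-level covariates (baseline SBP, a cognition composite, health
composites, log hair cortisol), yielding cross-level interaction terms such
as Tertile × Cognition.  Substituting level 2 into level 1 gives the
marginal form

$$y = X\beta + u_{0[\cdot]} + e, \qquad
  u_{0i} \sim N(0, \sigma^2_a), \quad e_{ti} \sim N(0, \sigma^2_e),$$

a Gaussian linear model with block covariance
$V = \sigma^2_a S_a + \sigma^2_e I_n$, where $S_a$ indicates same-subject
pairs.  Only a random intercept is supported: random slopes and crossed
designs are out of scope.  The parameters are
$\theta = (\beta, \sigma^2_a, \sigma^2_e)$; `tertile` is treated as a
continuous 1–12 time index so that a single slope and simple products
define the cross-level terms, and covariates enter on their supplied scale
(no silent standardization) so coefficients stay interpretable in raw
units.  Interactions are raw elementwise products of the uncentered
columns; this is what makes the simple-slopes arithmetic below exact.

All block operations (solves, log-determinants, quadratic forms) use the
Sherman–Morrison structure of each within-subject block
$\sigma^2_e I + \sigma^2_a \mathbf{1}\mathbf{1}'$ and run in $O(n)$; dense
materializations exist only in the test oracles.

# Generalized fiducial inference

The fiducial distribution is defined through the data-generating equation

$$Y = A(U, \theta) = X\beta + (\sigma^2_a S_a + \sigma^2_e I_n)^{1/2} U,
  \qquad U \sim N(0, I_n),$$

whose inversion transfers the randomness of $U$ to $\theta$ without a
prior.  The resulting density is proportional to the likelihood times a
Jacobian factor, $r_y(\theta) \propto f(y \mid \theta)\, J(y, \theta)$,
where for this model the parameter gradient of $A$ concatenates to

$$M = [\,X,\; S_a V^{-1} r,\; V^{-1} r\,], \qquad r = y - X\beta,$$

and $J$ is a determinant functional of $M$.  Two conventions circulate for
that functional: $\det(M'M)$ and $\sqrt{\det(M'M)}$.  The package defaults
to the square-root convention, $\log J = \tfrac12 \log\det(M'M)$, which is
the form under which the one-sample limit of the model reproduces the
classical fiducial result exactly — with $X$ an intercept column and the
random intercept disabled, the fiducial marginal of the mean is Student-t
with $n-1$ degrees of freedom and scale $s/\sqrt n$, and the test suite
verifies this by Kolmogorov–Smirnov comparison.  The non-root variant is
available via `root = FALSE` on `fid_log_jacobian()` and `fidlmm()` for
sensitivity analysis.  Constant factors in the gradient columns (the ½
from differentiating in the variances) are independent of $\theta$ and
cancel under normalization, so they are dropped.

Degenerate configurations ($r = 0$, which zeroes the two residual-derived
columns) give $\log J = -\infty$: a rejectable log-density value, not an
error, so the sampler simply never visits them.

## Sampling

`fidlmm()` samples $r_y(\theta)$ with an adaptive Gaussian random-walk
Metropolis algorithm on $(\beta, \log\sigma^2_a, \log\sigma^2_e)$; the
log-transform Jacobian terms $\log\sigma^2_a + \log\sigma^2_e$ are added to
the target.  Sampling the log variances keeps the $\sigma^2_a = 0$ boundary
unreachable — a deliberate interior parameterization (REML, by contrast,
may return exactly 0).  Chains initialize at the REML estimates, jittered
per chain; the proposal covariance is seeded from the numerical curvature
of the target at that point (with the GLS coefficient covariance as a
fallback) and only its global scale adapts during warmup, by a
Robbins–Monro update targeting an acceptance rate of 0.25–0.40.
Adaptation stops at the end of warmup, so the kept draws target the exact
density.  Defaults are 4 chains, 2,000 warmup and 5,000 kept iterations
per chain; identical seeds and configurations reproduce the draws exactly.
Split R-hat and an autocorrelation-based effective sample size are
reported per parameter; R-hat above 1.05 raises a recorded warning, not an
error.

Any correct sampler would do here — correctness is pinned by two oracles
in the test suite: the closed-form Student-t limit above, and a
2-parameter model whose MCMC marginals are compared against the
grid-normalized density.

## Summaries and decisions

Point estimates are draw means; intervals are equal-tailed empirical
quantiles (not HPD), matching ordinary confidence-interval semantics and
available for *all* parameters, variance components included.  The
null-effect rule follows equivalence-test logic: an effect is `nonnull`
when its interval excludes 0, `null` when the interval contains 0 and lies
entirely within $(-b, +b)$ for an analyst-supplied equivalence bound $b$,
and `inconclusive` otherwise.  No default bound is ever applied silently —
a reasonable choice is a fraction of the response SD, but it belongs to
the analyst.

The property that motivates the method — approximate frequentist validity
without asymptotics — is checked directly: over 300 synthetic replications
at 28 subjects × 18 observations, the empirical coverage of nominal 95%
fiducial intervals for every fixed effect must lie in [0.90, 0.99].

# Frequentist companion

`fit_reml()` implements REML for the same model.  Because there is a
single variance ratio $\phi = \sigma^2_a / \sigma^2_e$, the criterion is
profiled analytically down to one dimension: for fixed $\phi$ the GLS
coefficients and $\hat\sigma^2_e$ are closed-form, and the profiled
deviance is minimized by golden-section search on $\log\phi$ over
$[-30, 15]$, with the $\phi = 0$ boundary evaluated explicitly and chosen
when it is at least as good.  This replaces the more generic
two-dimensional multi-start optimization one would use for richer
random-effect structures; for a lone random intercept the 1-D profile is
exact, deterministic, and has no convergence failures to manage.

Coefficient t-tests use Satterthwaite degrees of freedom:
$\nu_j = 2 c_j^2 / \widehat{\mathrm{Var}}(c_j)$ with
$c_j(\sigma^2_a, \sigma^2_e)$ the coefficient variance, its gradient taken
numerically, and the variance-component covariance from the observed REML
information (forward differences at the $\sigma^2_a = 0$ boundary).
Kenward–Roger is intentionally not offered.  Variance-component standard
errors are reported from the observed information on the variance scale;
they are descriptive and not directly comparable to intervals.
Non-positive df estimates fall back to $n - p$ with a logged warning; in
the single-level limit $n - p$ is exact and used directly.

`variance_partition()` fits the unconditional model and reports the
within/between shares $\sigma^2_e / (\sigma^2_e + \tau_{00})$ as
percentages.  `simple_slopes()` probes a cross-level interaction at the
moderator mean ± 1 SD, where the mean and SD are computed across persons
(one row per subject) because moderators are person-level; the slope is
$\beta_{\mathrm{focal}} + \beta_{\mathrm{int}} \cdot (\bar m \pm s_m)$
with a delta-method SE and Satterthwaite df for the same linear
combination.

The whole frequentist path is cross-validated in the test suite against
lme4/lmerTest on fixed benchmarks (coefficients to $10^{-6}$ relative,
variance components to $10^{-4}$); those packages are test-time oracles,
never runtime dependencies.

# Bayes factors

`jzs_compare()` reproduces the default-prior model-comparison workflow:
every marginality-respecting subset of the candidate fixed effects is
compared to the intercept-only null by a Bayes factor $K$.  Marginality
means an interaction enters only when every proper nonempty subset of its
factors is present; with the six-term structure (two cross-level
interactions) this yields 26 candidate models, and with the nine-term
structure (a three-way interaction and its lower-order terms) 76 — both
counts are verified against brute-force enumeration in the tests.  The
random intercept is a nuisance term retained in *every* candidate,
including the null, so the null is itself a multilevel model and its $K$
is identically 1.  Whether baseline SBP is forced into all candidates
cannot be decided from the published description; the default leaves it a
free main effect, and `always_include` makes it forceable.

The prior is the Jeffreys–Zellner–Siow structure: flat on the grand mean,
Jeffreys on $\sigma^2_e$, and on each standardized effect block a normal
prior with variance $g_j \sigma^2_e$ where
$g_j \sim \mathrm{Inv}\text{-}\chi^2$ scaled so the implied effect prior
is Cauchy with scale $r_j$.  Default scales follow the conventions of the
standard implementation of this prior: 0.5 for binary/categorical effects
("medium"), $\sqrt2/4$ for continuous covariates, and 1 for the
random-intercept block ("nuisance"); all are exposed in `jzs_scales()`
since the published analysis says only that defaults were used.
Internally the response is centered and the main-effect covariates are
z-scored, with interaction columns formed as products of the standardized
mains; this makes $K$ invariant to affine changes of covariate units
(property-tested), and no coefficients are ever reported from this module.

Conditional on $g$ the marginal likelihood is closed-form (a Woodbury
computation over the effect cross-products); the $g$ integral uses
adaptive quadrature in one or two dimensions and mode-centered
multivariate-t importance sampling above that, with a log-scale error
estimate returned, a four-fold budget retry when it exceeds tolerance, and
an error after that.  The two integration paths agree within their stated
errors on shared cases (tested).  Reproducing the published $K$
*magnitudes* (e.g. $10^{53}$-scale values) requires the original data and
is explicitly not attempted; the printed ratio arithmetic and subset
counts are what the package checks.  Ratio labels follow the common
heuristic — 10 and 20 as "substantial" and "strong" — applied
symmetrically through reciprocals; treat them as heuristics, not
calibrated cutoffs.

# Preprocessing

The preparation pipeline mirrors the published procedure for continuous
SBP monitoring: the baseline is the mean over the final 5 minutes (300 s)
of the rest window (shorter windows are used whole, with a warning); each
task level's 1 Hz samples are split into three contiguous near-equal
spans — when the length is not divisible by 3 the leftover seconds go to
the *earlier* spans, a policy the source leaves unspecified, chosen here
so span lengths differ by at most one and logged in the function
documentation; tertile means minus baseline give 12 SBP-R values per wave.
Timestamps are 0-based and marker intervals half-open, so spans tile each
level exactly (property-tested).  Hair-cortisol concentrations are
natural-log transformed (a base switch exists; the published description
does not specify the base).

Composite scores (cognition, physical/mental health challenges) use a
transparent signed z-mean — z-score each indicator across persons, apply
the declared orientation, average, re-center — **as a documented
substitute** for the original confirmatory factor scores, whose loadings
are unpublished.  The substitute reproduces near-zero means by
construction but cannot and does not try to reproduce the published
factor-score SDs.

# The synthetic generator

`simulate_dataset()` is the test bed for everything above, and its
defaults *are* the study conditions: 28 subjects, 2 waves × 12 tertiles,
rows removed completely at random with probability 0.25 so the expected
row count is 504 of 672 (the true missingness mechanism is unknown; MCAR
is the neutral choice), an unconditional truth with $\tau_{00} = 125.97$,
$\sigma^2_e = 131.22$ (the published variance partition, ~49%/51%), an
intercept of 4.41 (the published mean SBP-R), and person covariates drawn
at the published between-person moments.  Wave-2 covariates are generated
mean-reverting from wave 1 with correlation 0.7 — a plausible six-month
stability for health composites, chosen once and not revisited.
Conditional models are simulated by passing a spec and coefficient vector;
the response is assembled exactly by the level-1/level-2 algebra, so
noise-free simulation regresses back to the coefficients at machine
precision (tested).

What the generator emulates is the *statistical* structure: Gaussian
random intercepts, Gaussian residuals, person-level moderators,
cross-level products, MCAR missingness.  What it does not emulate:
beat-to-beat cardiovascular dynamics, autocorrelated within-task noise,
informative missingness, measurement error in the composites, or any
non-normality of real SBP-R.  Passing coverage and recovery tests
therefore certify the inferential machinery under the stated model, not
robustness to violations of it.  `simulate_trace()` generates 1 Hz traces
with a configurable engagement curve to exercise the preprocessing
end-to-end; `coverage_study()` wraps simulate–fit–cover loops with
failure logging.

# Numerical choices and problem sizes

* REML: profile search interval $\log\phi \in [-30, 15]$, tolerance
  $10^{-10}$; boundary tie broken toward $\phi = 0$.
* Finite differences: relative steps $10^{-4}$ (information),
  $10^{-5}$ (Satterthwaite gradients); forward at the
  $\sigma^2_a = 0$ boundary.
* Sampler: scale adaptation in batches of 50 during warmup only;
  proposal curvature fallback is a diagonal built from the GLS SEs.
* JZS: quadrature relative tolerances $10^{-7}$–$10^{-9}$; importance
  sampling with multivariate-t (df 5) proposals, covariance inflated by
  1.3, default 4,000 draws, log-error tolerance 0.05.
* Validation sizes, chosen to make the statistical checks sharp while the
  default suite stays quick: dense-oracle equivalence on 100+ random
  instances with $n \le 24$; coverage over 300 replications at
  28 × 18 observations with 2 chains × (400 + 500) iterations per fit;
  recovery at 200 subjects; KS oracles at 10,000+ draws.

# Known limitations

* Only a single random intercept; no random slopes, crossed effects, or
  the 3-level wave structure (the published wave-level variance test is
  not reproduced here).
* The equivalence bound of the null-effect rule is analyst-supplied;
  conclusions labeled "null" are relative to that bound.
* Bayes-factor magnitudes depend on the prior scales; only ratios and
  orderings should be interpreted, and only at the default scales unless
  deliberately varied.
* The composite scores are not factor scores; coefficients on them are
  not numerically comparable to analyses using the original instruments.
* Fiducial intervals carry Monte-Carlo error; for publication-grade
  intervals use the default (or larger) chain settings and check the
  reported R-hat and effective sample sizes.
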