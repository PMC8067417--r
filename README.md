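# fidlmm

Frequentist, Bayesian, and generalized fiducial inference for
random-intercept linear mixed models, side by side.

## The problem

Repeated-measures studies in aging and psychophysiology often have small
person-level samples — a few dozen participants, each observed many times.
A canonical example, and the package's motivating design, is cardiovascular
engagement monitoring: systolic blood-pressure responsivity (SBP-R, task
SBP minus resting baseline, mmHg) averaged within 12 tertiles of
time-on-task at each of 2 longitudinal waves, with person-level moderators
(cognition, physical and mental health composites, log hair cortisol).
With ~28 people, inference that leans on asymptotics is fragile, and
"p > 0.05" is not evidence of a null.  Running the same multilevel model
under three paradigms — and trusting effects where the paradigms agree —
is a practical robustness check.  `fidlmm` packages all three:

* **Generalized fiducial** (the core): a data-driven distribution on the
  parameters, obtained without a prior by inverting the data-generating
  equation, sampled by MCMC, with confidence intervals for *every*
  parameter including the variance components.
* **Frequentist**: REML with Satterthwaite t-tests, variance partition,
  simple slopes.
* **Bayesian**: Jeffreys–Zellner–Siow default-prior Bayes factors for all
  marginality-respecting subsets of the fixed effects against the
  intercept-only null.

## The model and the fiducial density

The two-level model, written marginally, is

    y = X beta + u0[subject] + e,   u0 ~ N(0, sigma2_a),  e ~ N(0, sigma2_e)

so `y ~ N(X beta, V)` with `V = sigma2_a * S_a + sigma2_e * I`, where `S_a`
flags same-subject pairs.  The fiducial distribution comes from the
data-generating equation `Y = A(U, theta) = X beta + V^{1/2} U` with
standard-normal `U`; its density is

    r_y(theta)  ∝  f(y | theta) · J(y, theta),

the Gaussian likelihood weighted by a Jacobian factor built from

    M = [ X,  S_a V^{-1} (y - X beta),  V^{-1} (y - X beta) ],

with `J = sqrt(det(M'M))` (a `root = FALSE` switch gives the non-root
variant).  `fidlmm()` samples this density with an adaptive random-walk
Metropolis algorithm on `(beta, log sigma2_a, log sigma2_e)`, initialized
at REML, and summarizes draws into equal-tailed interval estimates.  The
construction is validated against closed-form and grid oracles, and its
headline property — near-nominal frequentist coverage without asymptotics —
is checked by simulation in the test suite.

## Worked example

Simulate a study-sized dataset (28 subjects, 2 waves × 12 tertiles, ~25%
of rows missing at random) with a known six-term truth, then fit it both
ways:

```r
library(fidlmm)

cfg <- synthetic_config(
  spec = as_model_spec(sbp_r ~ tertile + sbp_baseline + cognition +
                         physical_w1 + tertile:cognition +
                         tertile:physical_w1),
  beta = c(5.82, -0.33, 0.22, -11.82, -6.59, 0.32, 0.13),
  seed = 1)
sim <- simulate_dataset(cfg)          # 503 rows on this seed

freq <- fit_reml(cfg$spec, sim$table)
summary(freq)
#>            parameter  estimate      se     df       t         p sig
#>          (Intercept)  35.81000 13.6600  24.02  2.6210 0.0149700   *
#>              tertile  -0.56280  0.1636 472.90 -3.4410 0.0006307 ***
#>         sbp_baseline   0.01692  0.1015  23.68  0.1666 0.8691000
#>            cognition -15.11000  3.1800  37.89 -4.7520 0.0000289 ***
#>          physical_w1  -7.84400  3.5390  40.63 -2.2170 0.0323100   *
#>    tertile:cognition   0.56440  0.2246 472.70  2.5130 0.0123100   *
#>  tertile:physical_w1   0.06008  0.2503 472.90  0.2401 0.8104000
#>  ...
#>  var_subject    99.78 31.460
#>    var_resid   152.70  9.941

fid <- fidlmm(cfg$spec, sim$table, chains = 4, warmup = 1000,
              keep = 2000, seed = 1)
print(fid, digits = 3)
#>            parameter estimate   lower   upper
#>          (Intercept)  35.8000   4.310  64.000
#>              tertile  -0.5850  -0.927  -0.264
#>         sbp_baseline   0.0173  -0.189   0.249
#>            cognition -15.2000 -21.200  -8.820
#>          physical_w1  -7.7200 -15.500  -0.446
#>    tertile:cognition   0.5750   0.126   1.020
#>  tertile:physical_w1   0.0307  -0.500   0.557
#>          var_subject 112.0000  54.800 201.000
#>            var_resid 154.0000 135.000 176.000
```

The two paradigms agree here: the time slope, cognition, physical
challenges, and the Tertile × Cognition interaction are recovered (the
generating values sit inside every interval), and the fiducial fit
additionally intervals the variance components.  Probe the interaction and
apply the equivalence-style null rule:

```r
simple_slopes(freq, "tertile", "cognition")
#>      at moderator_value   slope    se  df      t        p
#>  -1 SD          -0.584 -0.8921 0.228 473 -3.907 0.000107
#>  +1 SD           0.838 -0.0895 0.225 473 -0.399 0.690264

null_effect_decision(fid, "tertile:cognition", equivalence_bound = 1)
#> [1] "nonnull"
```

SBP-R declines over the task for people one SD below the cognition mean
but is flat one SD above it.  For model comparison, `jzs_compare()` ranks
all marginality-respecting subsets of the candidate terms (26 models for
this six-term set) by Bayes factor against the intercept-only null, and
`variance_partition()` gives the unconditional within/between split.

A YAML-driven orchestrator (`run_analysis()`) and a thin shell wrapper
(`inst/cli/fidlmm`) run the same stages — `simulate`, `prep` (raw 1 Hz
trace preprocessing into per-tertile SBP-R), `fit-freq`, `fit-fiducial`,
`compare-bayes`, `report` — and write tidy CSVs plus a side-by-side
report.

## Layout

* `R/design.R`, `R/covariance.R` — model specs, design realization, block
  covariance and likelihood
* `R/fiducial.R` — Jacobian, fiducial density, sampler, summaries,
  null-effect rule
* `R/reml.R` — profiled REML, Satterthwaite tests, variance partition,
  simple slopes
* `R/bayes.R` — subset enumeration, JZS marginal likelihoods, comparison
* `R/dataprep.R` — trace preprocessing (baseline, tertiles, SBP-R,
  log-cortisol, composites)
* `R/synthetic.R` — generator and coverage studies
* `R/cli.R`, `inst/cli/fidlmm` — orchestration and command line
* `vignettes/fiducial-mixed-models.Rmd` — the methods account
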