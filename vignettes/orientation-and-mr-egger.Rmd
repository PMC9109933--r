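---
title: "SNP orientation and MR-Egger: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP orientation and MR-Egger: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrorient)
```

## The scientific problem

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure $X$ on an outcome $Y$ from per-SNP GWAS summary
statistics. Each of $m$ independent biallelic SNPs $G_j$ contributes an
estimated association with the exposure,
$(\hat\beta_{Xj}, \hat\sigma_{Xj})$, and with the outcome,
$(\hat\beta_{Yj}, \hat\sigma_{Yj})$, taken from non-overlapping cohorts.

The sign of every association estimate depends on which allele of the SNP
is chosen as the effect allele. This *orientation* (or *coding*) choice is
physically arbitrary — flipping SNP $j$ replaces
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ by
$(-\hat\beta_{Xj}, -\hat\beta_{Yj})$ — and one would hope no analysis
depends on it. MR-Egger regression, however, does: its causal estimate is
invariant only under the *global* flip of all SNPs, and changes when any
proper subset is re-oriented. Common MR software re-orients every SNP to be
positively associated with the exposure (the *default* coding). This
package exists to study, by simulation and by exact algebra, what that
convention does to MR-Egger and its relatives.

## The generating model

The simulator draws individual-level data from the structural model

$$X = \sum_{j=1}^m \beta_{Xj} G_j + U + \epsilon_X, \qquad
  Y = \sum_{j=1}^m \alpha_j G_j + \theta X + U + \epsilon_Y,$$

with $G_j \sim \text{Binomial}(2, \text{maf})$, a shared unmeasured
confounder $U$ and independent errors, all standard normal by default
(`maf = 0.3`). The direct (pleiotropic) effect $\alpha_j$ is non-zero for
invalid instruments. Summary statistics are the per-SNP simple-regression
slopes and standard errors, computed on an exposure cohort and an
independent outcome cohort that share the same realized effect vectors
$(\beta_X, \alpha)$ — the standard two-sample design. (Whether the cohorts
should also share the effect draws is not dictated by the model; sharing
them is the conventional reading and is what we implement.)

Three built-in effect scenarios differ in the support of $\beta_{Xj}$
under the *oracle* coding, the orientation in which the data are
generated:

* `"a"`: uniform on $(-0.2,-0.1)\cup(0.1,0.2)$ — mean zero;
* `"b"`: uniform on $(-0.1,-0.03)\cup(0.1,0.2)$ — mixed signs, non-zero
  mean;
* `"c"`: uniform on $(0.1,0.3)$ — all positive, so the default coding
  coincides with the oracle coding.

Union supports are sampled uniformly over the union as a set, i.e. the
interval is picked with probability proportional to its width (for
scenario `"b"` the negative interval has probability $0.07/0.17$).
A fraction `prop_invalid` of SNPs (the first `round(prop_invalid * m)` in
draw order, which is exchangeable) receive
$\alpha_j \sim N(0, 0.1^2)$ (*balanced*) or $N(0.1, 0.1^2)$
(*directional*) pleiotropy; the rest have $\alpha_j = 0$. Because
$\alpha$ and $\beta_X$ are drawn independently, the sample covariance
between them is not zero in any one replication but averages to zero
across replications — the *weak* InSIDE assumption, which holds by
construction only in the oracle coding.

## Estimators

All three estimators treat $\hat\beta_{Xj}$ as fixed covariates (the
no-measurement-error, NOME, convention) and are implemented as closed-form
normal-equation solves; the test suite checks them against independent
`solve()`-based fits to $10^{-12}$.

**IVW.** $\hat\theta_{\mathrm{IVW}} = \sum_j \hat\beta_{Yj}\hat\beta_{Xj}
\hat\sigma_{Yj}^{-2} \big/ \sum_j \hat\beta_{Xj}^2\hat\sigma_{Yj}^{-2}$,
the zero-intercept weighted regression. Numerator and denominator are both
even in the signs, so IVW is *exactly* invariant to any re-orientation —
the suite asserts bitwise equality across all $2^{m-1}$ codings at small
$m$. The fixed-effect variant uses variance
$1/\sum_j \hat\beta_{Xj}^2 \hat\sigma_{Yj}^{-2}$ with a normal reference;
the multiplicative random-effects variant inflates it by the residual
overdispersion $\hat\sigma_I^2$ (weighted RSS over $m-1$, floored at 1)
and uses a $t(m-1)$ reference.

**MR-Egger.** The same weighted regression with a free intercept $r$, the
weighted-average direct effect. Its slope equals
$\mathrm{cov}_w(\hat\beta_Y,\hat\beta_X)/\mathrm{var}_w(\hat\beta_X)$ and
converges to $\theta + \mathrm{cov}_w(\alpha,\beta_X)/
\mathrm{var}_w(\beta_X)$: consistent exactly when InSIDE holds *in the
coding being used*. `egger_plim()` evaluates this limit for any oriented
true-effect vectors and is used to confirm that simulated default-coding
bias matches its analytic prediction.

**Radial-Egger.** Ordinary least squares of
$\hat\theta_j\sqrt{w_j}$ on $\sqrt{w_j}$ with first-order weights
$w_j = \hat\beta_{Xj}^2/\hat\sigma_{Yj}^2$ (higher-order weights are out
of scope). Since the Wald ratio $\hat\theta_j$ and $w_j$ are both even in
the signs, Radial-Egger is coding-invariant — but the orientation is baked
in: $\sqrt{w_j} = |\hat\beta_{Xj}|/\hat\sigma_{Yj}$ is the
exposure-increasing coding in disguise, and in simulations Radial-Egger
tracks default-coding MR-Egger closely.

### Inference conventions

The overdispersion parameters are constrained to be $\ge 1$ (no
underdispersion), so estimated residual scales are floored at 1 before
standard errors are formed. Egger-type p-values use $t(m-2)$; IVW(RE) uses
$t(m-1)$; IVW(FE) uses the normal, as in fixed-effect meta-analysis. The
floor makes the Egger intercept test mildly conservative when the true
dispersion is exactly 1 (empirically ~0.04 rejection at the nominal 0.05
with $m = 100$, inside the Monte-Carlo band of the calibration test) —
the familiar price of a boundary-constrained variance. These conventions
are design choices of this package; reasonable software differs in the df
and reference used.

## Coding machinery

`coding_scheme()` is a $\pm 1$ sign vector. Since $s$ and $-s$ give the
same Egger slope, schemes are canonicalized by forcing the first sign to
$+1$; uniqueness claims (e.g. "99 unique random codings") are therefore
statements about the $2^{m-1}$ equivalence classes. `default_coding()`
maps an exact zero beta to $+1$ so it is deterministic (exact zeros have
probability zero in simulation). `random_codings()` draws on a dedicated
RNG scope keyed by its own seed, so coding sampling never perturbs
data-generation streams; when the request is dense relative to $2^{m-1}$
it switches to enumeration plus sampling without replacement, so
exhaustive requests are exact.

## Diagnostics

`inside_covariance()` is the weighted sample covariance between direct
effects and instrument strengths, with the sum-of-weights (population
$1/m$-type) denominator, matching the form in which the InSIDE condition
is stated; an equal-weights mode supports the algebraic identities used in
the property tests. `nome_i_squared()` computes
$Q = \sum_j (\hat\beta_{Xj}-\bar{\hat\beta}_X)^2/\hat\sigma_{Xj}^2$ and
$I^2 = (Q - (m-1))/Q$. A negative $I^2$ is reported as computed with a
flag, not truncated at zero — truncation would hide exactly the
diagnostic signal the statistic exists for. Because flipping to one sign
minimizes the dispersion of $\hat\beta_X$, the default coding provably
minimizes $I^2$ over all codings (asserted exhaustively in the tests),
which is why the default coding also maximizes NOME-violation
(regression-dilution) bias.

## The study drivers

`run_scenario()` runs replications of (draw effects, simulate two
cohorts, re-orient, fit, diagnose). One root seed spawns a table of
sub-seeds per replication for the effect draw, the cohort simulation and
the random-coding draw, so arms are reproducible independently. The
"random" coding arm uses one fresh random orientation per replication
rather than a single fixed one, so no single arbitrary coding dominates
the summary. A replication whose cohort draw degenerates (e.g. a
monomorphic SNP at small $n$) is retried up to 3 times with a fresh
sub-seed and the retry count is reported. Rejection rates are two-sided
at 0.05. $I^2$ is computed per replication and averaged.

`coding_sensitivity()` is the synthetic-data replacement for re-analyzing
published GWAS pairs: it fits MR-Egger under the default coding plus $k$
unique random codings of one dataset and tabulates the spread of estimates
and p-values. `irrelevant_iv_experiment()` appends $m_0$ irrelevant
instruments ($\beta_X = 0$) and contrasts fits and InSIDE covariances on
the core and augmented instrument sets; irrelevant instruments with
pleiotropy drawn from the same law as a *fully* invalid core leave the
mean covariance at zero (the mean-pleiotropy profile stays uniform), so
the experiment's interesting regimes are partial invalidity or
pleiotropy-free irrelevant instruments.

## Numerical and scale choices

The cohort simulation and per-SNP regression reduction run in compiled
code, holding genotypes as raw bytes and drawing
$\text{Binomial}(2,p)$ as a sum of two uniform comparisons on R's RNG
stream; `simulate_individuals()` + `gwas_summary()` provide the same
reduction in plain R for inspection (the two paths consume the RNG
differently, so they match in distribution, not draw-for-draw). The
package's reference scale for Monte-Carlo checks is $m = 100$,
$n = 100{,}000$ per cohort and 200 replications (100-plus for the $I^2$
checks), with means compared at 3 Monte-Carlo standard errors; smaller
problem sizes are used for purely algebraic properties, which hold at
$10^{-12}$ regardless of scale.

A `nome_exact` toggle replaces $\hat\beta_{Xj}$ by the true $\beta_{Xj}$
(with `se_exposure = 0`). This isolates orientation-induced InSIDE
violation from NOME violation: default-coding bias in the mixed-sign
scenario persists under `nome_exact`, demonstrating it is not a
measurement-error artifact; it also makes the simulated Egger mean match
`egger_plim()` directly, which is how the analytic bias prediction is
tested.

## What the generator does and does not emulate

It emulates independent biallelic SNPs at a common allele frequency,
normal confounding and noise, uncorrelated pleiotropy (the direct effects
are independent of instrument strengths under the oracle coding), and
exactly non-overlapping cohorts. It does **not** emulate linkage
disequilibrium, allele-frequency spectra, case-control outcomes, sample
overlap, winner's-curse instrument selection, or correlated pleiotropy
(direct effects acting through confounders). Passing tests therefore show
that the estimators and diagnostics behave as the theory predicts under
the stated model — not that MR-Egger is safe or unsafe on any particular
real trait pair, where these unmodeled features matter. Real-data
harmonization (strand flips, palindromic SNPs, reference panels) is out of
scope: orientation here is purely the sign convention of association
estimates, which is the object of study.

## Known limitations

* Only first-order radial weights; no modified second/third-order weights.
* No robust (median/mode/outlier-resistant) estimators; the point is the
  behavior of the Egger family itself.
* The intercept test inherits the mild conservatism of the floored
  overdispersion when the truth is at the boundary.
* `enumerate_codings()` refuses $m > 16$; exhaustive claims are only
  checked where exhaustion is feasible, and hold algebraically beyond.
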