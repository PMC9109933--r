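# mrorient

Tools for studying how the allele coding (orientation) of SNPs affects
MR-Egger regression and related two-sample Mendelian randomization (MR)
estimators.

## The problem

In two-sample MR, the causal effect θ of an exposure X on an outcome Y is
estimated from per-SNP GWAS summary statistics
(β̂_Xj, σ̂_Xj, β̂_Yj, σ̂_Yj). The sign of every association estimate
depends on which allele is taken as the effect allele — an arbitrary
bookkeeping choice. The inverse-variance weighted (IVW) estimator

θ̂_IVW = Σ_j β̂_Yj β̂_Xj σ̂_Yj⁻² / Σ_j β̂²_Xj σ̂_Yj⁻²

is exactly invariant to re-orienting SNPs. MR-Egger regression,

β̂_Yj = r + θ β̂_Xj + ε_Ej,  ε_Ej ~ N(0, σ²_E σ̂²_Yj),

is not: its slope survives only the global flip of all SNPs, and the
InSIDE assumption it needs (zero weighted covariance between direct
effects α_j and instrument strengths β_Xj) is tied to one particular —
unknown — *oracle* coding. The common software convention of orienting
every SNP to be positively associated with the exposure (the *default*
coding) silently assumes InSIDE holds in that specific orientation, and
also minimizes the I² = (Q − (m−1))/Q NOME diagnostic, maximizing
regression-dilution bias.

The package provides, for researchers and method developers in genetic
epidemiology:

* a simulator of individual-level data under the structural model
  X = Σ β_Xj G_j + U + ε_X, Y = Σ α_j G_j + θX + U + ε_Y, reduced to
  two-sample GWAS summary statistics (compiled kernel; n = 100,000-sized
  cohorts are cheap);
* from-scratch IVW (FE/RE), MR-Egger and Radial-Egger estimators;
* coding-scheme machinery: default / oracle / random / exhaustively
  enumerated orientations, unique up to global flip;
* InSIDE covariance, Q/I² NOME diagnostics, and the Egger intercept test;
* study drivers: Monte-Carlo scenario runs, a coding-sensitivity scan,
  and an irrelevant-instrument experiment.

## Worked example

Mixed-sign instrument strengths with a non-zero mean (scenario `"b"`),
30% invalid IVs with directional pleiotropy, true θ = 0.2:

```r
library(mrorient)

spec <- effect_spec("b", prop_invalid = 0.3, pleiotropy = "directional")
cfg <- scenario_config(spec, m = 100, n_exposure = 50000, n_outcome = 50000,
                       theta = 0.2, reps = 100, seed = 1,
                       methods = c("IVW_RE", "EGGER", "RADIAL_EGGER"),
                       codings = c("oracle", "default"))
run_scenario(cfg)
#> scenario result: 100 reps, m = 100, n = 50000/50000, theta = 0.2 (0 retries)
#>         method  coding reps mean_slope sd_slope      bias    rmse reject_rate
#> 1        EGGER default  100     0.6725  0.12386  0.472475 0.48828        1.00
#> 4        EGGER  oracle  100     0.1989  0.06260 -0.001119 0.06229        0.84
#> 2       IVW_RE default  100     0.3138  0.05189  0.113808 0.12497        1.00
#> 5       IVW_RE  oracle  100     0.3138  0.05189  0.113808 0.12497        1.00
#> 3 RADIAL_EGGER default  100     0.6735  0.12356  0.473471 0.48917        1.00
#> 6 RADIAL_EGGER  oracle  100     0.6735  0.12356  0.473471 0.48917        1.00
#>   mean_i_squared mean_inside_cov    mc_se
#> 1         0.9498       1.201e-03 0.012386
#> 4         0.9895      -1.609e-05 0.006260
#> 2         0.9498       1.201e-03 0.005189
#> 5         0.9895      -1.609e-05 0.005189
#> 3         0.9498       1.201e-03 0.012356
#> 6         0.9895      -1.609e-05 0.012356
```

Reading the table: MR-Egger in the *oracle* coding is essentially
unbiased (mean 0.199 for θ = 0.2). The *default* exposure-increasing
coding shifts its mean to 0.67 — the re-orientation breaks InSIDE
(`mean_inside_cov` moves from ~0 to 1.2e-3, and bias ≈ cov/var of the
re-oriented effects) and compresses I² from 0.99 to 0.95. IVW is biased
here too (directional pleiotropy with non-zero mean instrument strength)
but identically so in every coding, and Radial-Egger reproduces
default-coding Egger in *any* coding because its weights absorb the
orientation.

The same dependence on one dataset:

```r
model <- draw_true_model(spec, m = 100, theta = 0.2, seed = 42)
d <- simulate_two_sample(model, 50000, 50000, seed = 43)
scan <- coding_sensitivity(d, k = 99, seed = 7)
range(scan$slope)
#> [1] 0.2078247 0.5598355
```

One hundred orientations of the *same* summary data move the MR-Egger
estimate from 0.21 to 0.56.

A command-line front end over these functions is installed at
`inst/scripts/mrorient` (subcommands `estimate`, `diagnose`,
`scan-codings`, `study`, `irrelevant-iv`).

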