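#' Specification of SNP effect distributions
#'
#' Describes the distributions that generate per-SNP exposure effects and
#' pleiotropic (direct) effects under the oracle coding. Three named
#' scenarios are built in, differing in the support of the SNP-exposure
#' effects beta_X:
#'
#' * `"a"`: uniform on (-0.2, -0.1) U (0.1, 0.2) — symmetric, mean zero;
#' * `"b"`: uniform on (-0.1, -0.03) U (0.1, 0.2) — mixed signs, non-zero
#'   mean;
#' * `"c"`: uniform on (0.1, 0.3) — all positive, so the default
#'   exposure-increasing coding coincides with the oracle coding.
#'
#' For union supports the interval is chosen with probability proportional
#' to its width, then the value uniformly within it, i.e. beta_X is uniform
#' over the union as a set. A fraction `prop_invalid` of SNPs are invalid
#' instruments whose direct effect alpha on the outcome is drawn
#' `N(0, 0.1^2)` (`"balanced"` pleiotropy) or `N(0.1, 0.1^2)`
#' (`"directional"`); valid SNPs have alpha = 0.
#'
#' @param scenario `"a"`, `"b"`, `"c"`, or `"custom"` (then supply
#'   `beta_support`).
#' @param prop_invalid fraction of invalid IVs in `[0, 1]`.
#' @param pleiotropy `"balanced"` or `"directional"`.
#' @param beta_support for `scenario = "custom"`: a list of numeric
#'   `c(lower, upper)` intervals forming the support of beta_X.
#' @param alpha_mean,alpha_sd mean and SD of the direct-effect law on
#'   invalid IVs; defaults follow the pleiotropy tag (mean 0 or 0.1,
#'   SD 0.1).
#' @return An `effect_spec` object.
#' @examples
#' effect_spec("b", prop_invalid = 0.3, pleiotropy = "directional")
#' @export
effect_spec <- function(scenario = c("a", "b", "c", "custom"),
                        prop_invalid = 0.3,
                        pleiotropy = c("balanced", "directional"),
                        beta_support = NULL, alpha_mean = NULL,
                        alpha_sd = 0.1) {
  scenario <- match.arg(scenario)
  pleiotropy <- match.arg(pleiotropy)
  if (is.null(beta_support)) {
    beta_support <- switch(scenario,
      a = list(c(-0.2, -0.1), c(0.1, 0.2)),
      b = list(c(-0.1, -0.03), c(0.1, 0.2)),
      c = list(c(0.1, 0.3)),
      custom = stop("scenario = 'custom' requires `beta_support`")
    )
  } else if (scenario != "custom") {
    stop("`beta_support` may only be supplied with scenario = 'custom'")
  }
  for (iv in beta_support) {
    if (length(iv) != 2L || !is.numeric(iv) || diff(iv) <= 0)
      stop("each support interval must be numeric c(lower, upper) with ",
           "positive width")
  }
  if (!is.numeric(prop_invalid) || prop_invalid < 0 || prop_invalid > 1)
    stop("prop_invalid must lie in [0, 1]")
  if (is.null(alpha_mean))
    alpha_mean <- if (pleiotropy == "directional") 0.1 else 0
  stopifnot(alpha_sd >= 0)
  structure(
    list(scenario = scenario, prop_invalid = prop_invalid,
         pleiotropy = pleiotropy, beta_support = beta_support,
         alpha_mean = alpha_mean, alpha_sd = alpha_sd),
    class = "effect_spec"
  )
}

#' True generating model for a two-sample MR simulation
#'
#' Holds the parameters of the structural model
#' \deqn{X = \sum_j \beta_{Xj} G_j + U + \epsilon_X, \qquad
#'       Y = \sum_j \alpha_j G_j + \theta X + U + \epsilon_Y,}
#' with `G_j ~ Binomial(2, maf_j)` and `U`, `eps_X`, `eps_Y` independent
#' zero-mean normals. `beta_x` and `alpha` are expressed under the oracle
#' coding — the coding in which the effect distributions of
#' [effect_spec()] apply and the (weak) InSIDE assumption holds by
#' construction.
#'
#' @param theta causal effect of the exposure on the outcome.
#' @param beta_x length-m vector of SNP-exposure effects.
#' @param alpha length-m vector of direct SNP-outcome effects.
#' @param maf minor-allele frequency, a scalar or length-m vector in
#'   `(0, 0.5]` (default 0.3).
#' @param confounder_sd,eps_x_sd,eps_y_sd standard deviations of the
#'   confounder and the error terms (all default 1).
#' @param invalid optional logical vector flagging the invalid IVs.
#' @return A `true_model` object.
#' @export
true_model <- function(theta, beta_x, alpha, maf = 0.3, confounder_sd = 1,
                       eps_x_sd = 1, eps_y_sd = 1, invalid = NULL) {
  m <- length(beta_x)
  if (length(alpha) != m)
    stop("beta_x and alpha must have the same length")
  if (length(maf) == 1L) maf <- rep(maf, m)
  if (length(maf) != m) stop("maf must be scalar or length m")
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(c(confounder_sd, eps_x_sd, eps_y_sd) <= 0))
    stop("all noise SDs must be positive")
  if (is.null(invalid)) invalid <- alpha != 0
  structure(
    list(theta = theta, beta_x = as.numeric(beta_x),
         alpha = as.numeric(alpha), maf = maf,
         confounder_sd = confounder_sd, eps_x_sd = eps_x_sd,
         eps_y_sd = eps_y_sd, invalid = invalid, m = m),
    class = "true_model"
  )
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf(
    "true causal model: m = %d SNPs, theta = %g, %d invalid IVs\n",
    x$m, x$theta, sum(x$invalid)))
  invisible(x)
}

#' Draw a true model from an effect specification
#'
#' Draws the per-SNP exposure effects i.i.d. from the scenario's support
#' and flags `round(prop_invalid * m)` SNPs (the first in draw order, which
#' is exchangeable) as invalid, giving them direct effects from the
#' pleiotropy law; all other SNPs get alpha = 0.
#'
#' @param spec an [effect_spec()].
#' @param m number of SNPs (>= 3).
#' @param theta causal effect.
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @param maf,confounder_sd,eps_x_sd,eps_y_sd passed to [true_model()].
#' @return A [true_model()].
#' @export
draw_true_model <- function(spec, m, theta, seed = NULL, maf = 0.3,
                            confounder_sd = 1, eps_x_sd = 1, eps_y_sd = 1) {
  stopifnot(inherits(spec, "effect_spec"), m >= 3)
  local_seed(seed, {
    widths <- vapply(spec$beta_support, diff, numeric(1))
    lo <- vapply(spec$beta_support, `[`, numeric(1), 1L)
    idx <- sample.int(length(widths), m, replace = TRUE,
                      prob = widths / sum(widths))
    beta_x <- lo[idx] + runif(m) * widths[idx]
    n_invalid <- round(spec$prop_invalid * m)
    alpha <- numeric(m)
    if (n_invalid > 0)
      alpha[seq_len(n_invalid)] <- rnorm(n_invalid, spec$alpha_mean,
                                         spec$alpha_sd)
    true_model(theta, beta_x, alpha, maf = maf,
               confounder_sd = confounder_sd, eps_x_sd = eps_x_sd,
               eps_y_sd = eps_y_sd,
               invalid = seq_len(m) <= n_invalid)
  })
}

#' Simulate individual-level data from a true model
#'
#' Generates one cohort of `n` individuals: a genotype matrix with
#' `G_ij ~ Binomial(2, maf_j)`, and exposure and outcome assembled exactly
#' per the structural model, with the same confounder draw entering both.
#' Intended for inspection and small-scale checks; the two-sample
#' summary-statistics pipeline uses a compiled kernel that never
#' materializes the genotype matrix in R.
#'
#' @param model a [true_model()].
#' @param n cohort size.
#' @param seed integer seed, or `NULL`.
#' @return A list with `genotypes` (an `n x m` integer matrix), `exposure`
#'   and `outcome` (length-n numeric vectors).
#' @export
simulate_individuals <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "true_model"), n >= 1)
  local_seed(seed, {
    m <- model$m
    G <- matrix(rbinom(n * m, 2L, rep(model$maf, each = n)), n, m)
    U <- rnorm(n, 0, model$confounder_sd)
    X <- as.vector(G %*% model$beta_x) + U +
      rnorm(n, 0, model$eps_x_sd)
    Y <- as.vector(G %*% model$alpha) + model$theta * X + U +
      rnorm(n, 0, model$eps_y_sd)
    list(genotypes = G, exposure = X, outcome = Y)
  })
}

#' Per-SNP GWAS summary statistics by simple linear regression
#'
#' For each SNP, regresses the trait on the genotype dosage and returns the
#' slope `cov(trait, G_j) / var(G_j)` and its standard error (residual
#' variance with the usual n - 2 denominator). This is the reduction from
#' individual-level data to GWAS summary statistics.
#'
#' @param genotypes `n x m` numeric/integer genotype matrix.
#' @param trait length-n numeric trait vector.
#' @return A data.frame with columns `beta` and `se`, one row per SNP.
#' @export
gwas_summary <- function(genotypes, trait) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  stopifnot(length(trait) == n, n > 2)
  gsum <- colSums(G)
  sxx <- colSums(G * G) - gsum^2 / n
  mono <- which(sxx <= 0)
  if (length(mono))
    stop("monomorphic SNP(s) with zero genotype variance at index: ",
         paste(mono, collapse = ", "))
  tbar <- mean(trait)
  sxy <- as.vector(crossprod(G, trait)) - gsum * tbar
  beta <- sxy / sxx
  tss <- sum((trait - tbar)^2)
  rss <- pmax(tss - beta^2 * sxx, 0)
  data.frame(beta = beta, se = sqrt(rss / ((n - 2) * sxx)))
}

#' Simulate a two-sample GWAS summary dataset
#'
#' Generates two independent, non-overlapping cohorts from the same
#' [true_model()], computes exposure-side summary statistics from cohort
#' 1's `(G, X)` and outcome-side statistics from cohort 2's `(G, Y)`, and
#' returns them as a [summary_dataset()] in the oracle coding.
#'
#' With `nome_exact = TRUE` the estimated exposure-side effects are
#' replaced by the true `beta_x` (with `se_exposure = 0`), which isolates
#' orientation effects from exposure-side measurement error: it makes the
#' no-measurement-error (NOME) assumption hold exactly, at the cost of the
#' I-squared diagnostic becoming undefined.
#'
#' @param model a [true_model()].
#' @param n_exposure,n_outcome cohort sizes (>= 3).
#' @param seed integer root seed (two cohort sub-seeds are derived from
#'   it), or `NULL`.
#' @param nome_exact replace estimated exposure effects by the true ones.
#' @return A [summary_dataset()] with SNP ids `snp_001`, `snp_002`, ...
#' @export
simulate_two_sample <- function(model, n_exposure, n_outcome, seed = NULL,
                                nome_exact = FALSE) {
  stopifnot(inherits(model, "true_model"), n_exposure >= 3, n_outcome >= 3)
  seeds <- derive_seeds(seed, 2L)
  exposure <- local_seed(seeds[1L], cohort_gwas_cpp(
    as.integer(n_exposure), model$beta_x, model$alpha, model$theta,
    model$maf, model$confounder_sd, model$eps_x_sd, model$eps_y_sd,
    outcome = FALSE))
  outcome <- local_seed(seeds[2L], cohort_gwas_cpp(
    as.integer(n_outcome), model$beta_x, model$alpha, model$theta,
    model$maf, model$confounder_sd, model$eps_x_sd, model$eps_y_sd,
    outcome = TRUE))
  beta_exposure <- if (nome_exact) model$beta_x else exposure$beta
  se_exposure <- if (nome_exact) rep(0, model$m) else exposure$se
  summary_dataset(
    snp = sprintf("snp_%03d", seq_len(model$m)),
    beta_exposure = beta_exposure,
    se_exposure = se_exposure,
    beta_outcome = outcome$beta,
    se_outcome = outcome$se
  )
}
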