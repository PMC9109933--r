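# Independent fitting oracles: direct solves of the normal equations via
# base solve(), kept separate from the package's closed-form estimators so
# the two routes can disagree.

# weighted least squares of y on (1, x); returns coef and covariance pieces
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * y))
  rss <- sum(w * (y - X %*% coef)^2)
  list(intercept = coef[1L], slope = coef[2L], rss = rss,
       inv = solve(XtWX))
}

# zero-intercept weighted least squares slope
wls0_oracle <- function(x, y, w) {
  sum(w * x * y) / sum(w * x^2)
}

toy_dataset <- function(m = 6, seed = 101, alleles = FALSE) {
  set.seed(seed)
  summary_dataset(
    snp = sprintf("rs%d", seq_len(m)),
    beta_exposure = round(runif(m, -0.3, 0.3), 3),
    se_exposure = round(runif(m, 0.005, 0.02), 4),
    beta_outcome = round(runif(m, -0.1, 0.1), 3),
    se_outcome = round(runif(m, 0.01, 0.05), 4),
    effect_allele = if (alleles) sample(c("A", "C", "G", "T"), m, TRUE),
    other_allele = if (alleles) sample(c("A", "C", "G", "T"), m, TRUE)
  )
}

# dataset lying exactly on beta_y = intercept + slope * beta_x
exact_line_dataset <- function(intercept, slope, beta_x,
                               se_outcome = NULL) {
  m <- length(beta_x)
  if (is.null(se_outcome)) se_outcome <- seq(0.01, 0.03, length.out = m)
  summary_dataset(
    snp = sprintf("rs%d", seq_len(m)),
    beta_exposure = beta_x,
    beta_outcome = intercept + slope * beta_x,
    se_outcome = se_outcome,
    se_exposure = rep(0.01, m)
  )
}
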