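#' Weighted InSIDE covariance
#'
#' The InSIDE (Instrument Strength Independent of Direct Effect)
#' assumption, for a given SNP set and coding, states that the weighted
#' sample covariance between the direct effects alpha and the SNP-exposure
#' effects beta_X is zero:
#' \deqn{\mathrm{cov}_w(\alpha, \beta_X) = \frac{\sum_j
#'   \hat\sigma_{Yj}^{-2} (\alpha_j - \bar\alpha)(\beta_{Xj} -
#'   \bar\beta_X)}{\sum_j \hat\sigma_{Yj}^{-2}},}
#' with weighted means and a sum-of-weights denominator (the population,
#' 1/m-type normalization). With `se_outcome = NULL` all weights are equal,
#' which is the unweighted form used in equal-variance analyses.
#'
#' The quantity is exactly invariant under a global flip (negating every
#' alpha and beta_X) but changes, in general, when only a subset of SNPs is
#' flipped — which is precisely how re-orienting SNPs breaks InSIDE.
#'
#' @param alpha vector of direct effects.
#' @param beta_x vector of SNP-exposure effects (same length, m >= 2).
#' @param se_outcome optional vector of outcome-side SEs giving weights
#'   `1/se_outcome^2`; `NULL` for equal weights.
#' @return The weighted covariance, a number.
#' @export
inside_covariance <- function(alpha, beta_x, se_outcome = NULL) {
  m <- length(alpha)
  if (length(beta_x) != m)
    stop("alpha and beta_x must have the same length")
  if (m < 2) stop("need at least 2 SNPs")
  w <- if (is.null(se_outcome)) {
    rep(1, m)
  } else {
    if (length(se_outcome) != m)
      stop("se_outcome must have the same length as alpha")
    if (any(se_outcome <= 0)) stop("se_outcome must be strictly positive")
    1 / se_outcome^2
  }
  sw <- sum(w)
  abar <- sum(w * alpha) / sw
  bbar <- sum(w * beta_x) / sw
  sum(w * (alpha - abar) * (beta_x - bbar)) / sw
}

#' Q and I-squared NOME diagnostics
#'
#' Quantifies the violation of the no-measurement-error (NOME) assumption
#' on the exposure-side estimates via the heterogeneity statistic
#' \deqn{Q = \sum_j (\hat\beta_{Xj} - \bar{\hat\beta}_X)^2 /
#'       \hat\sigma_{Xj}^2,}
#' where the mean is weighted by `1/se_exposure^2`, and
#' `I^2 = (Q - (m - 1)) / Q`, the estimated fraction of the dispersion of
#' the exposure estimates that is real signal rather than estimation noise.
#' `I^2` near 1 means NOME is nearly satisfied; smaller values signal
#' regression-dilution bias in MR-Egger. Because the default
#' exposure-increasing coding compresses the betas onto one sign, it
#' minimizes the dispersion and hence yields the smallest I-squared among
#' all coding schemes.
#'
#' A negative value (Q < m - 1) is reported as computed, with
#' `flag = "negative"`, rather than truncated; when Q = 0 (all betas equal)
#' I-squared is undefined and reported as `NA` with `flag = "undefined"`.
#'
#' @param beta_exposure vector of exposure association estimates (m >= 2).
#' @param se_exposure vector of their standard errors, all strictly
#'   positive (under exact NOME the statistic is undefined and an error is
#'   raised).
#' @return A list with `q_stat`, `i_squared` and `flag` (one of `"ok"`,
#'   `"negative"`, `"undefined"`).
#' @export
nome_i_squared <- function(beta_exposure, se_exposure) {
  m <- length(beta_exposure)
  if (length(se_exposure) != m)
    stop("beta_exposure and se_exposure must have the same length")
  if (m < 2) stop("need at least 2 SNPs")
  if (any(se_exposure <= 0))
    stop("I-squared is undefined under exact NOME: all se_exposure must ",
         "be strictly positive")
  w <- 1 / se_exposure^2
  bbar <- sum(w * beta_exposure) / sum(w)
  q <- sum((beta_exposure - bbar)^2 * w)
  if (q == 0)
    return(list(q_stat = 0, i_squared = NA_real_, flag = "undefined"))
  i2 <- (q - (m - 1)) / q
  list(q_stat = q, i_squared = i2,
       flag = if (i2 < 0) "negative" else "ok")
}

#' Test of the MR-Egger intercept
#'
#' Two-sided test of H0: r = 0 (no average directional pleiotropy under
#' the coding in use) from an Egger-type fit, using the t reference with
#' the fit's residual degrees of freedom (m - 2). A rejection suggests the
#' presence of invalid IVs with directional pleiotropic effects — under
#' the coding the fit was given.
#'
#' @param fit an [mr_estimate()] with method `"EGGER"` or
#'   `"RADIAL_EGGER"` (IVW fits constrain the intercept to zero and are
#'   rejected).
#' @return The two-sided p-value.
#' @export
intercept_test <- function(fit) {
  if (!inherits(fit, "mr_estimate"))
    stop("`fit` must be an mr_estimate")
  if (!fit$method %in% c("EGGER", "RADIAL_EGGER"))
    stop("method mismatch: the intercept test applies to EGGER or ",
         "RADIAL_EGGER fits, not ", fit$method)
  2 * pt(-abs(fit$intercept / fit$intercept_se), df = fit$df)
}

#' One-row diagnostics summary for a dataset
#'
#' Convenience wrapper computing the NOME diagnostics, the Egger intercept
#' test, and — when the true effects are supplied (e.g. from the
#' simulator) — the weighted InSIDE covariance.
#'
#' @param data a [summary_dataset()].
#' @param alpha,beta_x optional true effect vectors in the same coding as
#'   `data`.
#' @return A one-row data.frame with columns `inside_cov`, `q_stat`,
#'   `i_squared`, `i_squared_flag`, `intercept_p`.
#' @export
mr_diagnostics <- function(data, alpha = NULL, beta_x = NULL) {
  validate_summary_dataset(data)
  nome <- if (all(data$se_exposure > 0)) {
    nome_i_squared(data$beta_exposure, data$se_exposure)
  } else {
    list(q_stat = NA_real_, i_squared = NA_real_, flag = "undefined")
  }
  inside <- if (!is.null(alpha)) {
    if (is.null(beta_x)) beta_x <- data$beta_exposure
    inside_covariance(alpha, beta_x, data$se_outcome)
  } else {
    NA_real_
  }
  data.frame(
    inside_cov = inside, q_stat = nome$q_stat, i_squared = nome$i_squared,
    i_squared_flag = nome$flag,
    intercept_p = intercept_test(mr_egger(data)),
    stringsAsFactors = FALSE
  )
}
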