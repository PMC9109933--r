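# All fits treat the exposure-side estimates as fixed covariates (the NOME
# convention of summary-data MR) and weight by the inverse outcome-side
# variance. Closed-form normal equations are used throughout; nothing here
# depends on lm()/lm.wfit so the estimators are self-contained and testable
# against independent solvers.

#' Inverse-variance weighted (IVW) estimator
#'
#' The IVW estimator is the inverse-variance weighted average of the
#' per-SNP Wald ratios, equivalently the zero-intercept weighted
#' least-squares regression of outcome on exposure associations with
#' weights `1/se_outcome^2`:
#' \deqn{\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}
#'   \hat\sigma_{Yj}^{-2}}{\sum_j \hat\beta_{Xj}^2 \hat\sigma_{Yj}^{-2}}.}
#'
#' The fixed-effect (`"FE"`) variant uses variance
#' `1 / sum(beta_x^2 / se_y^2)` and a normal reference; the multiplicative
#' random-effects (`"RE"`) variant inflates it by the residual
#' overdispersion (weighted RSS / (m - 1), floored at 1) and uses a
#' t(m - 1) reference. Both share the same point estimate, which is
#' invariant to any re-orientation of the SNPs.
#'
#' @param data a [summary_dataset()] (m >= 2; not all `beta_exposure`
#'   zero).
#' @param variant `"RE"` (default) or `"FE"`.
#' @return An [mr_estimate()] with `method` `"IVW_RE"` or `"IVW_FE"`.
#' @export
mr_ivw <- function(data, variant = c("RE", "FE")) {
  variant <- match.arg(variant)
  validate_summary_dataset(data)
  bx <- data$beta_exposure
  by <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  m <- length(bx)
  if (all(bx == 0))
    stop("degenerate instruments: all SNP-exposure associations are zero")
  denom <- sum(bx^2 * w)
  slope <- sum(by * bx * w) / denom
  fe_var <- 1 / denom
  disp <- max(1, sum(w * (by - slope * bx)^2) / (m - 1))
  if (variant == "FE") {
    se <- sqrt(fe_var)
    p <- 2 * pnorm(-abs(slope / se))
    mr_estimate("IVW_FE", slope, se, p, overdispersion = 1,
                df = m - 1L, n_snps = m)
  } else {
    se <- sqrt(disp * fe_var)
    p <- 2 * pt(-abs(slope / se), df = m - 1)
    mr_estimate("IVW_RE", slope, se, p, overdispersion = disp,
                df = m - 1L, n_snps = m)
  }
}

# weighted least squares of y on (1, x): returns the 2x2 solution plus the
# pieces needed for SEs; denominators use the sum of weights throughout
wls_fit <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= 0 || sxx / sw < 1e-24)
    stop("collinearity: weighted variance of the exposure associations ",
         "is zero")
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss <- sum(w * (y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss, sw = sw,
       xbar = xbar, sxx = sxx)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome associations on the
#' exposure associations with a free intercept,
#' \deqn{\hat\beta_{Yj} = r + \theta \hat\beta_{Xj} + \epsilon_{Ej}, \quad
#'       \epsilon_{Ej} \sim N(0, \sigma_E^2 \hat\sigma_{Yj}^2),}
#' with weights `1/se_outcome^2`. The slope is the causal-effect estimate
#' and the intercept the weighted-average direct (pleiotropic) effect. The
#' multiplicative overdispersion `sigma_E^2 >= 1` is estimated as the
#' weighted residual sum of squares over m - 2 and floored at 1; standard
#' errors are scaled by its square root and p-values use a t(m - 2)
#' reference.
#'
#' Unlike IVW, the Egger slope is not invariant to re-orienting a subset of
#' the SNPs; only the global flip of all SNPs leaves it unchanged (and
#' negates the intercept).
#'
#' @param data a [summary_dataset()] with m >= 3 and non-constant
#'   `beta_exposure`.
#' @return An [mr_estimate()] with `method = "EGGER"`.
#' @export
mr_egger <- function(data) {
  validate_summary_dataset(data)
  m <- nrow(data)
  if (m < 3)
    stop("MR-Egger needs at least 3 SNPs; got ", m)
  w <- 1 / data$se_outcome^2
  fit <- wls_fit(data$beta_exposure, data$beta_outcome, w)
  disp <- max(1, fit$rss / (m - 2))
  # (X'WX)^{-1} for design (1, x): slope var = 1/sxx,
  # intercept var = 1/sw + xbar^2/sxx
  slope_se <- sqrt(disp / fit$sxx)
  intercept_se <- sqrt(disp * (1 / fit$sw + fit$xbar^2 / fit$sxx))
  slope_p <- 2 * pt(-abs(fit$slope / slope_se), df = m - 2)
  intercept_p <- 2 * pt(-abs(fit$intercept / intercept_se), df = m - 2)
  mr_estimate("EGGER", fit$slope, slope_se, slope_p,
              intercept = fit$intercept, intercept_se = intercept_se,
              intercept_p = intercept_p, overdispersion = disp,
              df = m - 2L, n_snps = m)
}

#' Radial-Egger regression
#'
#' Egger-type regression on the radial scale: with first-order weights
#' `w_j = beta_x_j^2 / se_y_j^2` and per-SNP Wald ratios
#' `theta_j = beta_y_j / beta_x_j`, fits the unweighted regression
#' \deqn{\hat\theta_j \sqrt{w_j} = r' + \theta \sqrt{w_j} + \epsilon_{Rj}}
#' by ordinary least squares. The slope estimates the causal effect and the
#' intercept `r'` is the radial analogue of the Egger intercept. Standard
#' errors use the same overdispersion floor (residual variance floored at
#' 1) and t(m - 2) reference as [mr_egger()].
#'
#' @param data a [summary_dataset()] with m >= 3 and all `beta_exposure`
#'   nonzero.
#' @return An [mr_estimate()] with `method = "RADIAL_EGGER"`.
#' @export
mr_radial_egger <- function(data) {
  validate_summary_dataset(data)
  m <- nrow(data)
  if (m < 3)
    stop("Radial-Egger needs at least 3 SNPs; got ", m)
  zero <- data$beta_exposure == 0
  if (any(zero))
    stop("Wald ratio undefined (beta_exposure = 0) for SNP(s): ",
         paste(data$snp[zero], collapse = ", "))
  sqw <- abs(data$beta_exposure) / data$se_outcome        # sqrt(w_j)
  resp <- (data$beta_outcome / data$beta_exposure) * sqw  # theta_j sqrt(w_j)
  fit <- wls_fit(sqw, resp, rep(1, m))
  disp <- max(1, fit$rss / (m - 2))
  slope_se <- sqrt(disp / fit$sxx)
  intercept_se <- sqrt(disp * (1 / fit$sw + fit$xbar^2 / fit$sxx))
  slope_p <- 2 * pt(-abs(fit$slope / slope_se), df = m - 2)
  intercept_p <- 2 * pt(-abs(fit$intercept / intercept_se), df = m - 2)
  mr_estimate("RADIAL_EGGER", fit$slope, slope_se, slope_p,
              intercept = fit$intercept, intercept_se = intercept_se,
              intercept_p = intercept_p, overdispersion = disp,
              df = m - 2L, n_snps = m)
}

#' Asymptotic (probability-limit) MR-Egger slope
#'
#' For given true effects, the MR-Egger slope converges (in the GWAS sample
#' size) to
#' \deqn{\theta + \mathrm{cov}_w(\alpha, \beta_X) /
#'       \mathrm{var}_w(\beta_X),}
#' the causal effect plus the InSIDE-violation bias term. Used as an
#' analytic predictor of simulation bias under any re-orientation of the
#' true effect vectors.
#'
#' @param theta true causal effect.
#' @param beta_x,alpha true effect vectors (in the coding of interest).
#' @param weights positive weights (e.g. `1/se_outcome^2`); equal weights
#'   by default.
#' @return The asymptotic slope, a number.
#' @export
egger_plim <- function(theta, beta_x, alpha, weights = NULL) {
  m <- length(beta_x)
  stopifnot(length(alpha) == m)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights > 0))
  sw <- sum(weights)
  bbar <- sum(weights * beta_x) / sw
  abar <- sum(weights * alpha) / sw
  vb <- sum(weights * (beta_x - bbar)^2) / sw
  if (vb <= 0)
    stop("collinearity: weighted variance of beta_x is zero")
  cab <- sum(weights * (alpha - abar) * (beta_x - bbar)) / sw
  theta + cab / vb
}
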