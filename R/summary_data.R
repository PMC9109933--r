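#' Harmonized two-sample MR summary dataset
#'
#' Container for per-SNP two-sample GWAS summary statistics: the estimated
#' association of each SNP with the exposure and with the outcome, together
#' with their standard errors and (optionally) allele labels. This is the
#' common currency of all estimators and diagnostics in the package.
#'
#' The exposure-side standard error may be zero, which encodes the
#' no-measurement-error (NOME) idealization in which the SNP-exposure
#' associations are treated as known; the estimators ignore `se_exposure`
#' either way, but the I-squared NOME diagnostic requires it to be positive.
#'
#' @param snp character vector of unique SNP identifiers.
#' @param beta_exposure numeric vector of SNP-exposure association estimates
#'   (trait units per effect allele).
#' @param beta_outcome numeric vector of SNP-outcome association estimates.
#' @param se_outcome numeric vector of outcome-side standard errors
#'   (strictly positive).
#' @param se_exposure numeric vector of exposure-side standard errors
#'   (non-negative; defaults to 0, i.e. exact NOME).
#' @param effect_allele,other_allele optional character vectors of
#'   single-letter allele labels; supply both or neither.
#' @return A `summary_dataset`, a `data.frame` with one row per SNP.
#' @examples
#' d <- summary_dataset(
#'   snp = c("rs1", "rs2", "rs3"),
#'   beta_exposure = c(0.12, -0.08, 0.15),
#'   beta_outcome = c(0.03, -0.01, 0.04),
#'   se_outcome = c(0.01, 0.012, 0.011)
#' )
#' nrow(d)
#' @export
summary_dataset <- function(snp, beta_exposure, beta_outcome, se_outcome,
                            se_exposure = 0, effect_allele = NULL,
                            other_allele = NULL) {
  m <- length(snp)
  if (length(se_exposure) == 1L) se_exposure <- rep(se_exposure, m)
  out <- data.frame(
    snp = as.character(snp),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    stringsAsFactors = FALSE
  )
  if (!is.null(effect_allele) || !is.null(other_allele)) {
    if (is.null(effect_allele) || is.null(other_allele))
      stop("supply both `effect_allele` and `other_allele`, or neither")
    out$effect_allele <- as.character(effect_allele)
    out$other_allele <- as.character(other_allele)
  }
  class(out) <- c("summary_dataset", "data.frame")
  validate_summary_dataset(out)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("Two-sample MR summary dataset: %d SNPs%s\n", nrow(x),
              if (has_alleles(x)) " (with allele labels)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more SNPs\n", nrow(x) - 6L))
  invisible(x)
}

has_alleles <- function(data) {
  all(c("effect_allele", "other_allele") %in% names(data))
}

validate_summary_dataset <- function(data) {
  req <- c("snp", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("summary dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- nrow(data)
  if (m < 3L)
    stop("a summary dataset needs at least 3 SNPs (Egger regression has ",
         "zero residual degrees of freedom below that); got ", m)
  num <- req[-1L]
  for (col in num) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]]) ||
        any(!is.finite(data[[col]])))
      stop("column `", col, "` must be finite numeric with no missing values")
  }
  if (anyDuplicated(data$snp))
    stop("SNP identifiers must be unique; duplicated: ",
         paste(unique(data$snp[duplicated(data$snp)]), collapse = ", "))
  bad_se <- data$se_outcome <= 0
  if (any(bad_se))
    stop("se_outcome must be strictly positive; offending SNP(s): ",
         paste(data$snp[bad_se], collapse = ", "))
  if (any(data$se_exposure < 0))
    stop("se_exposure must be non-negative; offending SNP(s): ",
         paste(data$snp[data$se_exposure < 0], collapse = ", "))
  invisible(data)
}

tsv_columns <- c("snp", "beta_exposure", "se_exposure", "beta_outcome",
                 "se_outcome", "effect_allele", "other_allele")

#' Read a harmonized summary-statistics TSV
#'
#' Reads a tab-delimited file with a header row into a [summary_dataset()].
#' Columns are matched by name, in any order; `effect_allele` and
#' `other_allele` are optional, and `se_exposure` defaults to 0 (exact NOME)
#' when absent. Rows with a missing value in any required numeric field are
#' dropped with a warning reporting their row indices.
#'
#' @param path path to a tab-delimited file with columns `snp`,
#'   `beta_exposure`, `beta_outcome`, `se_outcome` and optionally
#'   `se_exposure`, `effect_allele`, `other_allele`.
#' @return A validated [summary_dataset()].
#' @seealso [write_summary_tsv()]
#' @export
read_summary_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
  req <- c("snp", "beta_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("summary TSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"se_exposure" %in% names(raw)) raw$se_exposure <- 0
  numeric_req <- c("beta_exposure", "se_exposure", "beta_outcome",
                   "se_outcome")
  for (col in numeric_req) raw[[col]] <- as.numeric(raw[[col]])
  incomplete <- which(Reduce(`|`, lapply(raw[numeric_req], is.na)))
  if (length(incomplete)) {
    warning("dropping ", length(incomplete),
            " row(s) with missing required numeric fields (row indices: ",
            paste(incomplete, collapse = ", "), ")")
    raw <- raw[-incomplete, , drop = FALSE]
  }
  summary_dataset(
    snp = raw$snp,
    beta_exposure = raw$beta_exposure,
    beta_outcome = raw$beta_outcome,
    se_outcome = raw$se_outcome,
    se_exposure = raw$se_exposure,
    effect_allele = if ("effect_allele" %in% names(raw)) raw$effect_allele,
    other_allele = if ("other_allele" %in% names(raw)) raw$other_allele
  )
}

#' Write a summary dataset to TSV
#'
#' Serializes a [summary_dataset()] as a tab-delimited file with a header
#' row in the canonical column order. Numeric fields are written with 17
#' significant digits so that `read_summary_tsv(write_summary_tsv(d))`
#' round-trips doubles exactly. Allele columns are omitted when absent.
#'
#' @param data a [summary_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(data, path) {
  validate_summary_dataset(data)
  cols <- intersect(tsv_columns, names(data))
  out <- as.data.frame(data)[, cols, drop = FALSE]
  for (col in cols) {
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write summary TSV to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' MR estimate container
#'
#' Bundles the result of one summary-data MR fit: slope (the causal-effect
#' estimate), intercept (the average direct-effect term for Egger-type
#' fits), their standard errors and p-values, the estimated multiplicative
#' overdispersion, and the residual degrees of freedom.
#'
#' @param method one of `"IVW_FE"`, `"IVW_RE"`, `"EGGER"`, `"RADIAL_EGGER"`.
#' @param slope,slope_se,slope_p causal-effect estimate, SE, two-sided p.
#' @param intercept,intercept_se,intercept_p intercept estimate, SE and
#'   two-sided p (`NA` for IVW, whose intercept is constrained to zero).
#' @param overdispersion estimated multiplicative residual scale, floored
#'   at 1.
#' @param df residual degrees of freedom (m - 1 for IVW, m - 2 for
#'   Egger-type fits).
#' @param n_snps number of SNPs in the fit.
#' @return An object of class `mr_estimate`.
#' @keywords internal
#' @export
mr_estimate <- function(method, slope, slope_se, slope_p,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_p = NA_real_, overdispersion = 1,
                        df = NA_integer_, n_snps = NA_integer_) {
  method <- match.arg(method, c("IVW_FE", "IVW_RE", "EGGER", "RADIAL_EGGER"))
  structure(
    list(method = method, slope = slope, slope_se = slope_se,
         slope_p = slope_p, intercept = intercept,
         intercept_se = intercept_se, intercept_p = intercept_p,
         overdispersion = overdispersion, df = df, n_snps = n_snps),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit on %d SNPs (df = %d)\n", x$method, x$n_snps, x$df))
  cat(sprintf("  slope     %s (SE %s, p = %s)\n",
              format(x$slope, digits = digits),
              format(x$slope_se, digits = digits),
              format.pval(x$slope_p, digits = digits)))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept %s (SE %s, p = %s)\n",
                format(x$intercept, digits = digits),
                format(x$intercept_se, digits = digits),
                format.pval(x$intercept_p, digits = digits)))
  cat(sprintf("  overdispersion %s\n", format(x$overdispersion,
                                              digits = digits)))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, slope = x$slope, slope_se = x$slope_se,
             slope_p = x$slope_p, intercept = x$intercept,
             intercept_se = x$intercept_se, intercept_p = x$intercept_p,
             overdispersion = x$overdispersion, df = x$df,
             n_snps = x$n_snps, stringsAsFactors = FALSE)
}
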