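#' SNP coding (orientation) schemes
#'
#' A coding scheme is a vector of signs, one per SNP, declaring which allele
#' is used as the effect allele. Flipping SNP j (sign -1) negates its
#' exposure and outcome association estimates and swaps its allele labels;
#' standard errors are unaffected. The InSIDE assumption behind MR-Egger is
#' defined relative to one particular (unknown) "oracle" coding, which is
#' why the machinery here is a first-class object rather than a
#' preprocessing step.
#'
#' Because a global flip of all SNPs leaves the Egger slope unchanged (it
#' only negates the intercept), schemes are treated as equivalent up to
#' multiplication by -1; [canonicalize_coding()] fixes the first SNP's sign
#' to +1 to pick a representative of each equivalence class, so there are
#' 2^(m-1) distinct classes over m SNPs.
#'
#' @param signs numeric vector with entries in `{-1, +1}`, one per SNP.
#' @param label one of `"oracle"`, `"default"`, `"random"`, `"custom"`.
#' @return A `coding_scheme` object.
#' @examples
#' coding_scheme(c(1, -1, 1))
#' @export
coding_scheme <- function(signs, label = c("custom", "oracle", "default",
                                           "random")) {
  label <- match.arg(label)
  signs <- as.numeric(signs)
  if (!length(signs) || !all(signs %in% c(-1, 1)))
    stop("coding signs must all be -1 or +1")
  structure(list(signs = signs, label = label), class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("coding scheme [%s] over %d SNPs: %d flipped\n", x$label,
              length(x$signs), sum(x$signs == -1)))
  invisible(x)
}

#' @export
length.coding_scheme <- function(x) length(x$signs)

#' Canonicalize a coding scheme up to global flip
#'
#' Returns the representative of the `{s, -s}` equivalence class whose
#' first sign is +1.
#'
#' @param scheme a [coding_scheme()].
#' @return A [coding_scheme()] with `signs[1] == +1`.
#' @export
canonicalize_coding <- function(scheme) {
  if (scheme$signs[1L] == -1)
    scheme$signs <- -scheme$signs
  scheme
}

#' Apply a coding scheme to a summary dataset
#'
#' Re-orients the dataset: multiplies `beta_exposure` and `beta_outcome`
#' elementwise by the scheme's signs, leaves standard errors unchanged, and
#' swaps `effect_allele`/`other_allele` wherever the sign is -1.
#'
#' Applying the same scheme twice restores the original dataset exactly
#' (signs are involutive).
#'
#' @param data a [summary_dataset()].
#' @param scheme a [coding_scheme()] of the same length.
#' @return A re-oriented [summary_dataset()].
#' @export
apply_coding <- function(data, scheme) {
  validate_summary_dataset(data)
  if (length(scheme$signs) != nrow(data))
    stop("coding scheme has length ", length(scheme$signs),
         " but the dataset has ", nrow(data), " SNPs")
  s <- scheme$signs
  data$beta_exposure <- s * data$beta_exposure
  data$beta_outcome <- s * data$beta_outcome
  if (has_alleles(data)) {
    flip <- s == -1
    tmp <- data$effect_allele[flip]
    data$effect_allele[flip] <- data$other_allele[flip]
    data$other_allele[flip] <- tmp
  }
  data
}

#' The default (exposure-increasing) coding
#'
#' The orientation recommended and applied by common MR software: every SNP
#' is flipped, if needed, so that its association with the exposure is
#' positive. An exact zero association keeps its sign (+1) so the result is
#' deterministic.
#'
#' @param data a [summary_dataset()].
#' @return A [coding_scheme()] with label `"default"` such that
#'   `apply_coding(data, default_coding(data))` has all
#'   `beta_exposure >= 0`.
#' @export
default_coding <- function(data) {
  validate_summary_dataset(data)
  signs <- ifelse(data$beta_exposure < 0, -1, 1)
  coding_scheme(signs, label = "default")
}

coding_capacity <- function(m) 2^(m - 1)

coding_key <- function(signs) paste(ifelse(signs > 0, "+", "-"),
                                    collapse = "")

#' Random unique coding schemes
#'
#' Draws `k` coding schemes over `m` SNPs, pairwise distinct after
#' canonicalization up to global flip, reproducibly for a given seed. The
#' sampling uses its own RNG scope so it never perturbs a simulation
#' stream.
#'
#' @param m number of SNPs.
#' @param k number of schemes to draw; at most `2^(m-1)`, the number of
#'   distinct equivalence classes.
#' @param seed integer seed, or `NULL` to use the ambient RNG stream.
#' @return A list of `k` canonical [coding_scheme()]s with label
#'   `"random"`.
#' @export
random_codings <- function(m, k, seed = NULL) {
  stopifnot(m >= 1, k >= 1)
  cap <- coding_capacity(m)
  if (k > cap)
    stop("requested ", k, " codings but only ", cap,
         " distinct classes exist for m = ", m)
  local_seed(seed, {
    if (m <= 16 && k > cap / 2) {
      # dense request: enumerate the classes and sample without replacement
      all_schemes <- enumerate_codings(m)
      picked <- all_schemes[sample.int(cap, k)]
      lapply(picked, function(s) coding_scheme(s$signs, label = "random"))
    } else {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", k)
      got <- 0L
      while (got < k) {
        signs <- c(1, sample(c(-1, 1), m - 1L, replace = TRUE))
        key <- coding_key(signs)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- coding_scheme(signs, label = "random")
        }
      }
      out
    }
  })
}

#' Enumerate all coding classes
#'
#' All `2^(m-1)` canonical sign vectors over `m` SNPs, one per
#' global-flip equivalence class. Intended for exhaustive (brute-force)
#' checks at small `m`.
#'
#' @param m number of SNPs; at most 16.
#' @return A list of [coding_scheme()]s.
#' @export
enumerate_codings <- function(m) {
  stopifnot(m >= 1)
  if (m > 16)
    stop("refusing to enumerate 2^(m-1) codings for m = ", m,
         " (limit m <= 16)")
  if (m == 1L) return(list(coding_scheme(1)))
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m - 1L),
                                KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) {
    coding_scheme(c(1, grid[i, ]), label = "custom")
  })
}

#' Read / write a coding scheme as a one-column text file
#'
#' The file holds one `+1` or `-1` per line, in the same SNP order as the
#' dataset the scheme applies to.
#'
#' @param path file path.
#' @return `read_coding()` returns a [coding_scheme()] with label
#'   `"custom"`; `write_coding()` returns `path` invisibly.
#' @export
read_coding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- suppressWarnings(as.numeric(readLines(path)))
  if (anyNA(vals)) stop("coding file must contain only +1 / -1 values")
  coding_scheme(vals, label = "custom")
}

#' @rdname read_coding
#' @param scheme a [coding_scheme()].
#' @export
write_coding <- function(scheme, path) {
  writeLines(sprintf("%+d", as.integer(scheme$signs)), path)
  invisible(path)
}
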