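#' Configuration of a replication study
#'
#' Bundles everything needed to run a Monte-Carlo scenario: the effect
#' specification, problem sizes, causal effect, methods, coding arms, the
#' replication count and the root seed.
#'
#' @param spec an [effect_spec()].
#' @param m number of SNPs.
#' @param n_exposure,n_outcome cohort sizes for the two non-overlapping
#'   GWAS samples.
#' @param theta true causal effect.
#' @param reps number of Monte-Carlo replications (>= 1).
#' @param seed integer root seed; sub-seeds for effect draws, cohorts and
#'   coding sampling are derived from it.
#' @param methods subset of `c("IVW_FE", "IVW_RE", "EGGER",
#'   "RADIAL_EGGER")`.
#' @param codings subset of `c("oracle", "default", "random")`: `oracle`
#'   analyses the data in its generating orientation, `default` re-orients
#'   every SNP to be positively associated with the exposure, and `random`
#'   applies one fresh random orientation per replication.
#' @param nome_exact use the true exposure effects instead of their
#'   estimates (exact NOME; disables the I-squared diagnostic).
#' @param maf minor-allele frequency passed to the generator.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(spec, m, n_exposure, n_outcome, theta, reps,
                            seed = 1L,
                            methods = c("IVW_RE", "EGGER", "RADIAL_EGGER"),
                            codings = c("oracle", "default"),
                            nome_exact = FALSE, maf = 0.3) {
  stopifnot(inherits(spec, "effect_spec"), m >= 3, n_exposure >= 3,
            n_outcome >= 3, reps >= 1)
  methods <- match.arg(methods, c("IVW_FE", "IVW_RE", "EGGER",
                                  "RADIAL_EGGER"), several.ok = TRUE)
  codings <- match.arg(codings, c("oracle", "default", "random"),
                       several.ok = TRUE)
  structure(
    list(spec = spec, m = as.integer(m),
         n_exposure = as.integer(n_exposure),
         n_outcome = as.integer(n_outcome), theta = theta,
         reps = as.integer(reps), seed = as.integer(seed),
         methods = methods, codings = codings, nome_exact = nome_exact,
         maf = maf),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a YAML file
#'
#' Recognized keys: `scenario`, `prop_invalid`, `pleiotropy`, `m`,
#' `n_exposure`, `n_outcome`, `theta`, `reps`, `seed`, `methods`,
#' `codings`, `nome_exact`, `maf`.
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- effect_spec(
    scenario = cfg$scenario %||% "a",
    prop_invalid = cfg$prop_invalid %||% 0.3,
    pleiotropy = cfg$pleiotropy %||% "balanced"
  )
  scenario_config(
    spec, m = cfg$m, n_exposure = cfg$n_exposure,
    n_outcome = cfg$n_outcome, theta = cfg$theta %||% 0,
    reps = cfg$reps %||% 100L, seed = cfg$seed %||% 1L,
    methods = cfg$methods %||% c("IVW_RE", "EGGER", "RADIAL_EGGER"),
    codings = cfg$codings %||% c("oracle", "default"),
    nome_exact = isTRUE(cfg$nome_exact), maf = cfg$maf %||% 0.3
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_method <- function(data, method) {
  switch(method,
         IVW_FE = mr_ivw(data, "FE"),
         IVW_RE = mr_ivw(data, "RE"),
         EGGER = mr_egger(data),
         RADIAL_EGGER = mr_radial_egger(data))
}

scheme_for <- function(coding, data, m, seed) {
  switch(coding,
         oracle = coding_scheme(rep(1, m), label = "oracle"),
         default = default_coding(data),
         random = {
           s <- random_codings(m, 1L, seed = seed)[[1L]]
           s
         })
}

# one replication's dataset, retried (fresh sub-seed) if the cohort draw
# degenerates, e.g. a monomorphic SNP at small n
simulate_with_retry <- function(model, config, seed, max_tries = 3L) {
  for (try in seq_len(max_tries)) {
    dat <- tryCatch(
      simulate_two_sample(model, config$n_exposure, config$n_outcome,
                          seed = (seed + try - 1L) %% 2147483646L + 1L,
                          nome_exact = config$nome_exact),
      error = function(e) e
    )
    if (!inherits(dat, "error"))
      return(list(data = dat, retries = try - 1L))
  }
  stop("replication failed after ", max_tries, " attempts: ",
       conditionMessage(dat))
}

#' Run a Monte-Carlo scenario
#'
#' For each replication: draws a fresh [true_model()] from the effect
#' specification, simulates a two-sample summary dataset in the oracle
#' coding, then — for each requested coding arm — re-orients the data and
#' applies each requested estimator, recording the fit together with the
#' I-squared NOME diagnostic and the weighted InSIDE covariance of the
#' (re-oriented) true effects. Fully reproducible given the config's seed.
#'
#' @param config a [scenario_config()].
#' @return A `scenario_result`: a list with `records` (one row per
#'   replication x method x coding), `summary` (per method x coding
#'   aggregates, see [summarize_scenario()]), `config` and `retries`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  reps <- config$reps
  seeds <- local_seed(config$seed,
                      matrix(sample.int(2147483646L, reps * 3L), reps, 3L))
  n_arms <- length(config$methods) * length(config$codings)
  rows <- vector("list", reps * n_arms)
  retries <- 0L
  k <- 0L
  for (r in seq_len(reps)) {
    model <- draw_true_model(config$spec, config$m, config$theta,
                             seed = seeds[r, 1L], maf = config$maf)
    sim <- simulate_with_retry(model, config, seeds[r, 2L])
    retries <- retries + sim$retries
    dat <- sim$data
    for (coding in config$codings) {
      scheme <- scheme_for(coding, dat, config$m, seeds[r, 3L])
      coded <- apply_coding(dat, scheme)
      i2 <- if (all(coded$se_exposure > 0)) {
        nome_i_squared(coded$beta_exposure, coded$se_exposure)$i_squared
      } else {
        NA_real_
      }
      inside <- inside_covariance(scheme$signs * model$alpha,
                                  scheme$signs * model$beta_x,
                                  coded$se_outcome)
      for (method in config$methods) {
        fit <- fit_method(coded, method)
        k <- k + 1L
        rows[[k]] <- data.frame(
          rep = r, method = method, coding = coding, slope = fit$slope,
          slope_se = fit$slope_se, slope_p = fit$slope_p,
          intercept = fit$intercept, intercept_p = fit$intercept_p,
          i_squared = i2, inside_cov = inside, stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- do.call(rbind, rows)
  structure(
    list(records = records,
         summary = summarize_scenario(records, theta = config$theta),
         config = config, retries = retries),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "scenario result: %d reps, m = %d, n = %d/%d, theta = %g (%d retries)\n",
    cfg$reps, cfg$m, cfg$n_exposure, cfg$n_outcome, cfg$theta, x$retries))
  print(x$summary, digits = 4, ...)
  invisible(x)
}

#' Summarize per-replication records
#'
#' Aggregates per (method x coding): mean and empirical SD of the slope,
#' bias against the true effect, RMSE, empirical rejection rate of the
#' slope at the two-sided 0.05 level, mean I-squared and the Monte-Carlo
#' standard error of the mean slope (SD / sqrt(reps)). With a single
#' replication the SD-based columns are reported as `NA`.
#'
#' @param result a `scenario_result` or its `records` data.frame.
#' @param theta true causal effect; taken from the result's config when
#'   available.
#' @return A data.frame with one row per (method, coding).
#' @export
summarize_scenario <- function(result, theta = NULL) {
  records <- if (inherits(result, "scenario_result")) {
    if (is.null(theta)) theta <- result$config$theta
    result$records
  } else {
    result
  }
  if (is.null(theta))
    stop("supply `theta` when summarizing a bare records data.frame")
  if (!nrow(records)) stop("no records to summarize")
  groups <- split(records,
                  list(records$method, records$coding), drop = TRUE)
  out <- lapply(groups, function(g) {
    reps <- nrow(g)
    sdv <- if (reps > 1) sd(g$slope) else NA_real_
    data.frame(
      method = g$method[1L], coding = g$coding[1L], reps = reps,
      mean_slope = mean(g$slope), sd_slope = sdv,
      bias = mean(g$slope) - theta,
      rmse = sqrt(mean((g$slope - theta)^2)),
      reject_rate = mean(g$slope_p < 0.05),
      mean_i_squared = mean(g$i_squared),
      mean_inside_cov = mean(g$inside_cov),
      mc_se = if (reps > 1) sdv / sqrt(reps) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$coding), , drop = FALSE]
}

#' Coding-sensitivity scan for MR-Egger
#'
#' Fits MR-Egger under the default exposure-increasing coding plus `k`
#' random codings (unique up to global flip) and tabulates how the causal
#' estimate and its p-value move with the orientation of the SNPs. The
#' spread of the slopes across codings is the practical measure of how
#' coding-dependent the Egger conclusion is for this dataset.
#'
#' @param data a [summary_dataset()].
#' @param k number of random codings (>= 1; at most `2^(m-1) - 1`, the
#'   number of classes distinct from the default).
#' @param seed integer seed for the coding draws, or `NULL`.
#' @return A data.frame with columns `coding`, `slope`, `slope_p`,
#'   `intercept`, `intercept_p`, `is_default`, sorted by slope.
#' @export
coding_sensitivity <- function(data, k, seed = NULL) {
  validate_summary_dataset(data)
  stopifnot(k >= 1)
  m <- nrow(data)
  cap <- coding_capacity(m) - 1
  if (k > cap)
    stop("requested ", k, " random codings but only ", cap,
         " classes differ from the default for m = ", m)
  def <- canonicalize_coding(default_coding(data))
  def_key <- coding_key(def$signs)
  schemes <- local_seed(seed, {
    got <- list()
    keys <- character()
    # oversample to absorb collisions with the default class
    want <- k
    while (length(got) < k) {
      cand <- random_codings(m, min(want + 1, cap + 1))
      for (s in cand) {
        key <- coding_key(s$signs)
        if (key != def_key && !(key %in% keys) && length(got) < k) {
          got <- c(got, list(s))
          keys <- c(keys, key)
        }
      }
      want <- k - length(got)
    }
    got
  })
  all_schemes <- c(list(def), schemes)
  labels <- c("default", sprintf("random_%03d", seq_len(k)))
  rows <- mapply(function(s, lab) {
    fit <- mr_egger(apply_coding(data, s))
    data.frame(coding = lab, slope = fit$slope, slope_p = fit$slope_p,
               intercept = fit$intercept, intercept_p = fit$intercept_p,
               is_default = lab == "default", stringsAsFactors = FALSE)
  }, all_schemes, labels, SIMPLIFY = FALSE)
  res <- do.call(rbind, rows)
  res <- res[order(res$slope), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Irrelevant-instrument experiment
#'
#' Even when the oracle coding is known and InSIDE holds for the original
#' m instruments, adding `m0` irrelevant instruments (true
#' `beta_x = 0`) shifts the sample covariance between direct effects and
#' instrument strengths away from zero — unless the original exposure
#' effects sum to zero or the direct effects are balanced — and thereby
#' biases MR-Egger. Each replication simulates an augmented model with
#' `m + m0` SNPs and reports the oracle-coding Egger fit on the full
#' instrument set (`arm = "augmented"`, irrelevant IVs carrying direct
#' effects from the same pleiotropy law; `arm = "augmented_null"`,
#' irrelevant IVs with no direct effects) and on the first m SNPs alone
#' (`arm = "core"`), together with the weighted InSIDE covariance of the
#' instrument set each fit used.
#'
#' @param config a [scenario_config()] describing the original m-SNP
#'   scenario (the Egger estimator is forced; coding is oracle).
#' @param m0 number of irrelevant instruments to append (>= 0; with 0 the
#'   experiment reduces to the core arm only).
#' @return A `scenario_result`-like list with per-replication `records`
#'   (columns as in [run_scenario()] plus `arm`), a per-arm `summary`,
#'   `config` and `m0`.
#' @export
irrelevant_iv_experiment <- function(config, m0) {
  stopifnot(inherits(config, "scenario_config"), m0 >= 0)
  reps <- config$reps
  seeds <- local_seed(config$seed,
                      matrix(sample.int(2147483646L, reps * 3L), reps, 3L))
  arms <- if (m0 > 0) c("core", "augmented", "augmented_null") else "core"
  rows <- vector("list", reps * length(arms))
  k <- 0L
  for (r in seq_len(reps)) {
    model <- draw_true_model(config$spec, config$m, config$theta,
                             seed = seeds[r, 1L], maf = config$maf)
    alpha_extra <- local_seed(seeds[r, 3L],
                              rnorm(max(m0, 1L), config$spec$alpha_mean,
                                    config$spec$alpha_sd))[seq_len(m0)]
    for (arm in arms) {
      aug_alpha <- switch(arm,
        core = model$alpha,
        augmented = c(model$alpha, alpha_extra),
        augmented_null = c(model$alpha, rep(0, m0)))
      aug_model <- if (arm == "core") model else
        true_model(config$theta, c(model$beta_x, rep(0, m0)), aug_alpha,
                   maf = config$maf, confounder_sd = model$confounder_sd,
                   eps_x_sd = model$eps_x_sd, eps_y_sd = model$eps_y_sd)
      sim <- simulate_with_retry(aug_model, config, seeds[r, 2L])
      dat <- sim$data
      fit <- mr_egger(dat)
      inside <- inside_covariance(aug_model$alpha, aug_model$beta_x,
                                  dat$se_outcome)
      k <- k + 1L
      rows[[k]] <- data.frame(
        rep = r, arm = arm, method = "EGGER", coding = "oracle",
        slope = fit$slope, slope_se = fit$slope_se, slope_p = fit$slope_p,
        intercept = fit$intercept, intercept_p = fit$intercept_p,
        inside_cov = inside, stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, rows)
  groups <- split(records, records$arm)
  summ <- do.call(rbind, lapply(groups, function(g) {
    data.frame(arm = g$arm[1L], reps = nrow(g),
               mean_slope = mean(g$slope),
               bias = mean(g$slope) - config$theta,
               mean_inside_cov = mean(g$inside_cov),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(records = records, summary = summ, config = config,
                 m0 = as.integer(m0)),
            class = "irrelevant_iv_result")
}

#' @export
print.irrelevant_iv_result <- function(x, ...) {
  cat(sprintf("irrelevant-IV experiment: m = %d core + %d irrelevant, %d reps\n",
              x$config$m, x$m0, x$config$reps))
  print(x$summary, digits = 4, ...)
  invisible(x)
}
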