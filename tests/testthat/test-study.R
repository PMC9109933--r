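small_config <- function(scenario = "a", prop_invalid = 0.3,
                         pleiotropy = "directional", theta = 0.2,
                         reps = 5, seed = 7, m = 20, n = 2000, ...) {
  scenario_config(
    effect_spec(scenario, prop_invalid = prop_invalid,
                pleiotropy = pleiotropy),
    m = m, n_exposure = n, n_outcome = n, theta = theta, reps = reps,
    seed = seed, ...)
}

test_that("run_scenario is reproducible and its records are complete", {
  cfg <- small_config(methods = c("IVW_RE", "EGGER"),
                      codings = c("oracle", "default", "random"))
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 5 * 2 * 3)
  expect_false(anyNA(r1$records$slope))
  expect_false(anyNA(r1$records$i_squared))
})

test_that("IVW records are identical across coding arms within a replication", {
  cfg <- small_config(methods = "IVW_RE",
                      codings = c("oracle", "default", "random"))
  res <- run_scenario(cfg)
  by_rep <- split(res$records$slope, res$records$rep)
  for (slopes in by_rep)
    expect_true(all(slopes == slopes[1]))
})

test_that("all-positive generating effects make default and oracle coding coincide", {
  # n large enough that no estimated exposure beta crosses zero, so the
  # default re-orientation is exactly the identity
  cfg <- small_config(scenario = "c", prop_invalid = 1,
                      pleiotropy = "directional", n = 20000,
                      methods = "EGGER", codings = c("oracle", "default"))
  res <- run_scenario(cfg)
  oracle <- res$records[res$records$coding == "oracle", ]
  default <- res$records[res$records$coding == "default", ]
  expect_equal(oracle$slope, default$slope)
  expect_equal(oracle$intercept, default$intercept)
  expect_equal(oracle$i_squared, default$i_squared)
})

test_that("summaries report the documented aggregates", {
  cfg <- small_config(reps = 6, methods = c("IVW_RE", "EGGER"),
                      codings = "oracle")
  res <- run_scenario(cfg)
  s <- res$summary
  for (i in seq_len(nrow(s))) {
    g <- res$records[res$records$method == s$method[i] &
                       res$records$coding == s$coding[i], ]
    expect_equal(s$mean_slope[i], mean(g$slope))
    expect_equal(s$bias[i], mean(g$slope) - cfg$theta)
    expect_equal(s$rmse[i], sqrt(mean((g$slope - cfg$theta)^2)))
    expect_equal(s$reject_rate[i], mean(g$slope_p < 0.05))
    expect_equal(s$mc_se[i], sd(g$slope) / sqrt(nrow(g)))
  }
  one <- summarize_scenario(res$records[res$records$rep == 1, ],
                            theta = cfg$theta)
  expect_true(all(is.na(one$sd_slope)))
  expect_true(all(is.na(one$mc_se)))
})

test_that("analytic probability limit predicts the default-coding Egger bias", {
  spec <- effect_spec("b", prop_invalid = 0.3, pleiotropy = "directional")
  diffs <- vapply(1:40, function(r) {
    model <- draw_true_model(spec, m = 60, theta = 0.2, seed = 4000 + r)
    d <- simulate_two_sample(model, 20000, 20000, seed = 5000 + r,
                             nome_exact = TRUE)
    s <- default_coding(d)$signs
    plim <- egger_plim(0.2, s * model$beta_x, s * model$alpha,
                       weights = 1 / d$se_outcome^2)
    mr_egger(apply_coding(d, default_coding(d)))$slope - plim
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("coding_sensitivity scans unique codings and flags the default", {
  # exact through-origin relation: every coding returns the same slope
  d <- exact_line_dataset(0, 0.4, c(0.1, -0.2, 0.3, -0.15, 0.25))
  scan <- coding_sensitivity(d, k = 10, seed = 3)
  expect_equal(nrow(scan), 11)
  expect_equal(sum(scan$is_default), 1)
  expect_lt(diff(range(scan$slope)), 1e-10)

  # noisy data: slopes genuinely move with the coding
  d2 <- toy_dataset(m = 10, seed = 123)
  scan2 <- coding_sensitivity(d2, k = 50, seed = 4)
  expect_gt(diff(range(scan2$slope)), 1e-8)
  expect_false(is.unsorted(scan2$slope))

  # exhaustive k: the scan covers exactly the 2^(m-1) classes
  d5 <- toy_dataset(m = 5, seed = 124)
  scan5 <- coding_sensitivity(d5, k = 15, seed = 5)
  all_slopes <- sort(vapply(enumerate_codings(5), function(s) {
    mr_egger(apply_coding(d5, s))$slope
  }, numeric(1)))
  expect_equal(sort(scan5$slope), all_slopes, tolerance = 1e-12)
  expect_error(coding_sensitivity(d5, k = 16, seed = 5), "15")
})

test_that("irrelevant instruments break InSIDE unless the exposure effects are balanced", {
  # partial invalidity: the irrelevant IVs dilute the average direct effect
  # unevenly, so the covariance over the augmented set drifts from zero
  cfg <- small_config(scenario = "c", prop_invalid = 0.3,
                      pleiotropy = "directional", reps = 20, m = 15,
                      n = 1500, methods = "EGGER", codings = "oracle")
  res <- irrelevant_iv_experiment(cfg, m0 = 10)
  s <- res$summary
  core <- s[s$arm == "core", ]
  aug <- s[s$arm == "augmented", ]
  # expected augmented covariance ~ -0.0035 here; the core one stays near 0
  expect_gt(abs(aug$mean_inside_cov), 0.002)
  expect_lt(abs(core$mean_inside_cov), 0.002)

  # mean-zero exposure effects: adding irrelevant IVs leaves InSIDE intact
  cfg_a <- small_config(scenario = "a", prop_invalid = 1,
                        pleiotropy = "directional", reps = 20, m = 15,
                        n = 1500, methods = "EGGER", codings = "oracle")
  res_a <- irrelevant_iv_experiment(cfg_a, m0 = 10)
  ga <- res_a$records[res_a$records$arm == "augmented", ]
  expect_lt(abs(mean(ga$inside_cov)),
            3 * sd(ga$inside_cov) / sqrt(nrow(ga)) + 1e-3)

  # m0 = 0 reduces to the plain scenario run
  res0 <- irrelevant_iv_experiment(cfg, m0 = 0)
  plain <- run_scenario(cfg)
  expect_equal(res0$records$slope,
               plain$records$slope[plain$records$method == "EGGER"])
})

test_that("a YAML scenario config round-trips into scenario_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario: b", "prop_invalid: 0.3", "pleiotropy: directional",
    "m: 30", "n_exposure: 5000", "n_outcome: 4000", "theta: 0.2",
    "reps: 3", "seed: 11",
    "methods: [IVW_RE, EGGER]", "codings: [oracle, default]"), path)
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$m, 30L)
  expect_equal(cfg$n_outcome, 4000L)
  expect_identical(cfg$methods, c("IVW_RE", "EGGER"))
  expect_identical(cfg$spec$pleiotropy, "directional")
  res <- run_scenario(cfg)
  expect_equal(nrow(res$records), 3 * 2 * 2)
})
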