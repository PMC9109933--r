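test_that("IVW equals the weighted ratio estimator and its oracles", {
  d <- summary_dataset(
    snp = c("a", "b", "c"), beta_exposure = c(1, 1, 1),
    beta_outcome = c(2, 2, 2), se_outcome = c(1, 1, 1))
  expect_equal(mr_ivw(d, "FE")$slope, 2)

  d2 <- summary_dataset(
    snp = c("a", "b", "c"), beta_exposure = c(0.1, 0.2, 0.3),
    beta_outcome = c(0.05, 0.02, 0.09), se_outcome = c(0.1, 0.2, 0.1))
  w <- 1 / d2$se_outcome^2
  expect_equal(mr_ivw(d2)$slope,
               wls0_oracle(d2$beta_exposure, d2$beta_outcome, w),
               tolerance = 1e-12)

  zero <- summary_dataset(snp = letters[1:3], beta_exposure = rep(0, 3),
                          beta_outcome = 1:3, se_outcome = rep(1, 3))
  expect_error(mr_ivw(zero), "degenerate")
})

test_that("IVW slope and SE are exactly invariant under every coding", {
  for (m in c(4, 6, 8)) {
    d <- toy_dataset(m = m, seed = 30 + m)
    ref_fe <- mr_ivw(d, "FE")
    ref_re <- mr_ivw(d, "RE")
    for (s in enumerate_codings(m)) {
      coded <- apply_coding(d, s)
      fit <- mr_ivw(coded, "FE")
      expect_identical(fit$slope, ref_fe$slope)
      expect_identical(fit$slope_se, ref_fe$slope_se)
      fit_re <- mr_ivw(coded, "RE")
      expect_identical(fit_re$slope_se, ref_re$slope_se)
    }
  }
})

test_that("Egger recovers an exact linear relation and matches a WLS oracle", {
  d <- exact_line_dataset(0.5, 2, c(0.1, 0.25, 0.4, 0.6))
  fit <- mr_egger(d)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$overdispersion, 1)  # floored: residuals are zero

  d4 <- toy_dataset(m = 4, seed = 44)
  w <- 1 / d4$se_outcome^2
  oracle <- wls_oracle(d4$beta_exposure, d4$beta_outcome, w)
  fit4 <- mr_egger(d4)
  expect_equal(fit4$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit4$intercept, oracle$intercept, tolerance = 1e-12)
  disp <- max(1, oracle$rss / 2)
  expect_equal(fit4$slope_se, sqrt(disp * oracle$inv[2, 2]),
               tolerance = 1e-12)
  expect_equal(fit4$intercept_se, sqrt(disp * oracle$inv[1, 1]),
               tolerance = 1e-12)
  expect_equal(fit4$df, 2L)

  const <- summary_dataset(snp = letters[1:3], beta_exposure = rep(0.2, 3),
                           beta_outcome = c(0.1, 0.2, 0.3),
                           se_outcome = rep(0.1, 3))
  expect_error(mr_egger(const), "collinearity")
})

test_that("Egger slope survives the global flip (intercept negates) but not partial flips", {
  d <- toy_dataset(m = 6, seed = 55)
  ref <- mr_egger(d)
  flipped <- mr_egger(apply_coding(d, coding_scheme(rep(-1, 6))))
  expect_equal(flipped$slope, ref$slope, tolerance = 1e-12)
  expect_equal(flipped$intercept, -ref$intercept, tolerance = 1e-12)
  expect_equal(flipped$slope_se, ref$slope_se, tolerance = 1e-12)

  slopes <- vapply(enumerate_codings(6), function(s) {
    mr_egger(apply_coding(d, s))$slope
  }, numeric(1))
  expect_gt(max(abs(slopes - ref$slope)), 1e-6)
})

test_that("IVW is the intercept-constrained Egger fit, and they coincide at zero intercept", {
  d <- toy_dataset(m = 5, seed = 66)
  w <- 1 / d$se_outcome^2
  expect_equal(mr_ivw(d)$slope,
               wls0_oracle(d$beta_exposure, d$beta_outcome, w),
               tolerance = 1e-12)
  # data on a through-the-origin line: Egger fits intercept 0 and
  # reproduces the IVW slope
  d0 <- exact_line_dataset(0, 0.7, c(0.1, 0.2, 0.35, 0.5))
  eg <- mr_egger(d0)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$slope, mr_ivw(d0)$slope, tolerance = 1e-12)
})

test_that("Radial-Egger matches its transformed-variable oracle and exact fits", {
  d <- exact_line_dataset(0, 0.3, c(0.12, 0.2, 0.33, 0.41))
  fit <- mr_radial_egger(d)
  expect_equal(fit$slope, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  d3 <- toy_dataset(m = 3, seed = 77)
  sqw <- abs(d3$beta_exposure) / d3$se_outcome
  resp <- d3$beta_outcome / d3$beta_exposure * sqw
  oracle <- wls_oracle(sqw, resp, rep(1, 3))
  fit3 <- mr_radial_egger(d3)
  expect_equal(fit3$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit3$intercept, oracle$intercept, tolerance = 1e-12)

  dz <- toy_dataset(m = 4, seed = 78)
  dz$beta_exposure[2] <- 0
  expect_error(mr_radial_egger(dz), dz$snp[2])
})

test_that("egger_plim returns theta plus the weighted InSIDE bias term", {
  expect_equal(egger_plim(0.2, c(0.1, 0.2, 0.3), rep(0.5, 3)), 0.2)
  # alpha = beta: cov equals var, bias is exactly 1
  expect_equal(egger_plim(0.1, c(1, 2, 3), c(1, 2, 3)), 1.1)
  # hand-computed weighted case: w = (1, 1, 2)
  b <- c(1, 2, 4); a <- c(2, 1, 3); w <- c(1, 1, 2)
  bbar <- sum(w * b) / 4; abar <- sum(w * a) / 4
  bias <- sum(w * (a - abar) * (b - bbar)) / sum(w * (b - bbar)^2)
  expect_equal(egger_plim(0, b, a, w), bias, tolerance = 1e-12)
  expect_error(egger_plim(0, rep(1, 3), 1:3), "collinearity")
})

test_that("overdispersion is floored at one and reported df are correct", {
  d <- toy_dataset(m = 12, seed = 88)
  for (fit in list(mr_ivw(d, "FE"), mr_ivw(d, "RE"), mr_egger(d),
                   mr_radial_egger(d))) {
    expect_gte(fit$overdispersion, 1)
    expect_gte(fit$slope_se, 0)
    expect_true(fit$slope_p >= 0 && fit$slope_p <= 1)
  }
  expect_equal(mr_ivw(d)$df, 11L)
  expect_equal(mr_egger(d)$df, 10L)
  expect_equal(mr_radial_egger(d)$df, 10L)
})

test_that("Radial-Egger tracks default-coding Egger on mean-zero effect data", {
  spec <- effect_spec("a", prop_invalid = 0.3, pleiotropy = "directional")
  diffs <- vapply(1:30, function(r) {
    model <- draw_true_model(spec, m = 50, theta = 0.2, seed = 300 + r)
    d <- simulate_two_sample(model, 20000, 20000, seed = 600 + r)
    coded <- apply_coding(d, default_coding(d))
    mr_radial_egger(coded)$slope - mr_egger(coded)$slope
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(30) + 0.01)
})
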