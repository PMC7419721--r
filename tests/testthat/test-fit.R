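test_that("the MLE fit recovers a known observer from dense grid data", {
  obs <- ideal_observer(threshold = 40, beta = 1, lambda = 0)
  trials <- grid_trials(obs, 2^seq(2, 9, by = 0.5), n_per_level = 334,
                        seed = 10)
  est <- fit_stereo_threshold(trials, lambda_fixed = 0)
  expect_true(est$measurable)
  expect_gte(est$threshold, 36)
  expect_lte(est$threshold, 44)
})

test_that("chance-level data are flagged unmeasurable", {
  # responses at the guess rate carry no threshold information
  trials <- withr::with_seed(2, data.frame(
    disparity = rep(2^(2:10), each = 30),
    correct = runif(270) < 0.25))
  est <- fit_stereo_threshold(trials)
  expect_false(est$measurable)
  oest <- fit_stereo_threshold_oracle(trials)
  expect_false(oest$measurable)
})

test_that("the threshold criterion is definitional for lapse-free fits", {
  obs <- ideal_observer(threshold = 90, beta = 1.4, lambda = 0)
  trials <- grid_trials(obs, 2^seq(3, 10), n_per_level = 40, seed = 4)
  est <- fit_stereo_threshold(trials, lambda_fixed = 0)
  expect_true(est$measurable)
  p_at_thr <- 0.25 + 0.75 * pnorm((log2(est$threshold) - est$alpha) / est$beta)
  expect_equal(p_at_thr, 0.625, tolerance = 1e-12)
})

test_that("the fitted threshold is invariant to trial order", {
  obs <- ideal_observer(threshold = 60)
  trials <- grid_trials(obs, 2^seq(3, 9), n_per_level = 20, seed = 6)
  est1 <- fit_stereo_threshold(trials)
  est2 <- fit_stereo_threshold(trials[rev(seq_len(nrow(trials))), ])
  expect_equal(est1$threshold, est2$threshold)
  expect_equal(est1$log_likelihood, est2$log_likelihood)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_stereo_threshold(data.frame(disparity = rep(40, 30),
                                               correct = TRUE)),
               "distinct")
  expect_error(fit_stereo_threshold(data.frame(disparity = c(10, 20),
                                               correct = c(TRUE, FALSE))),
               "at least 20")
  expect_error(fit_stereo_threshold_oracle(
    data.frame(disparity = 2^(1:30), correct = TRUE), alpha_grid = numeric(0)),
    "non-empty")
})

test_that("optimizer and grid-search oracle agree on session data", {
  obs <- ideal_observer(threshold = 55, beta = 1.1, lambda = 0.01)
  lls <- t(vapply(1:15, function(i) {
    s <- run_stereo_session(obs, session_config(), seed = 600 + i)
    a <- fit_stereo_threshold(s$trials)
    b <- fit_stereo_threshold_oracle(s$trials)
    c(a$log_likelihood, b$log_likelihood,
      if (a$measurable && b$measurable) a$threshold / b$threshold else NA)
  }, numeric(3)))
  # the optimizer can only do better than or equal to the grid
  expect_true(all(lls[, 1] >= lls[, 2] - 1e-6))
  expect_true(all(abs(lls[, 1] - lls[, 2]) <= 0.05))
  expect_true(all(abs(log(lls[, 3])) <= log(1.05), na.rm = TRUE))
})

test_that("a one-point grid at the truth returns the truth", {
  obs <- ideal_observer(threshold = 40, beta = 1, lambda = 0)
  trials <- grid_trials(obs, 2^seq(3, 9), n_per_level = 10, seed = 3)
  est <- fit_stereo_threshold_oracle(trials, lambda_fixed = 0,
                                     alpha_grid = log2(40), beta_grid = 1)
  expect_equal(est$alpha, log2(40))
  expect_equal(est$beta, 1)
})

test_that("CR estimation recovers balanced and suppressed observers", {
  bal <- simulated_observer(cr_true = 1, sigma_cr = 0.3)
  tr <- withr::with_seed(5, {
    r <- 10^runif(200, -0.8, 0.8)
    data.frame(presented_ratio = r,
               reported_nondominant = runif(200) < cr_report_probability(bal, r))
  })
  est <- estimate_cr(tr)
  expect_true(est$converged)
  expect_gte(est$cr, 0.9); expect_lte(est$cr, 1.1)

  sup <- simulated_observer(cr_true = 10, sigma_cr = 0.3)
  tr2 <- withr::with_seed(6, {
    r <- 10^runif(500, 0.2, 1.8)
    data.frame(presented_ratio = r,
               reported_nondominant = runif(500) < cr_report_probability(sup, r))
  })
  est2 <- estimate_cr(tr2)
  expect_true(est2$converged)
  expect_gte(est2$cr, 8); expect_lte(est2$cr, 12.5)
})

test_that("one-sided letter reports do not converge", {
  tr <- data.frame(presented_ratio = 10^seq(-1, 1, length.out = 40),
                   reported_nondominant = TRUE)
  est <- estimate_cr(tr)
  expect_false(est$converged)
  expect_error(estimate_cr(data.frame(presented_ratio = -1,
                                      reported_nondominant = TRUE)),
               "positive")
})

test_that("full staircase sessions recover thresholds without material bias", {
  # parameter recovery through the complete pipeline: staircase-driven
  # placement, pooled MLE fit
  errs <- vapply(1:200, function(i) {
    obs <- withr::with_seed(3000 + i, {
      simulated_observer(psychometric_params(runif(1, log2(20), log2(500)),
                                             runif(1, 0.6, 1.8)),
                         kappa = 0.35)
    })
    s <- run_stereo_session(obs, session_config(), seed = 7000 + i)
    est <- fit_stereo_threshold(s$trials)
    if (!est$measurable) return(NA_real_)
    truth <- true_stereo_threshold(obs)$threshold
    log2(est$threshold) - log2(truth)
  }, numeric(1))
  expect_lt(mean(is.na(errs)), 0.1)
  expect_lte(median(abs(errs), na.rm = TRUE), 0.5)
  expect_lte(abs(mean(errs, na.rm = TRUE)), 0.25)
})
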