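test_that("stereo percent correct matches the 4AFC cumulative normal", {
  obs <- ideal_observer(threshold = 40, beta = 1, lambda = 0)
  # at the threshold disparity, equal contrast: midpoint of 0.25..1
  expect_equal(stereo_percent_correct(obs, 40, 80, 80), 0.625)
  # far below threshold performance falls to the guess rate
  expect_equal(stereo_percent_correct(obs, 1, 80, 80), 0.25,
               tolerance = 0.01)
  # a 10 percent dominant-eye decrement elevates the threshold by
  # 10^0.35 (about 2.24x): percent correct at the elevated threshold is
  # again 62.5 percent
  expect_equal(
    stereo_percent_correct(obs, 40 * 10^0.35, 80 * 0.9, 80), 0.625,
    tolerance = 1e-10)
})

test_that("stereo percent correct rejects out-of-range input", {
  obs <- ideal_observer()
  expect_error(stereo_percent_correct(obs, 0.5, 80, 80), "1, 4096")
  expect_error(stereo_percent_correct(obs, 5000, 80, 80), "1, 4096")
  expect_error(stereo_percent_correct(obs, 40, 0.5, 80), "1, 100")
  expect_error(stereo_percent_correct(obs, 40, 80, 120), "1, 100")
})

test_that("percent correct is monotone in disparity and imbalance", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      obs <- simulated_observer(
        stereo = psychometric_params(runif(1, log2(20), log2(1000)),
                                     runif(1, 0.3, 3),
                                     lambda = runif(1, 0, 0.1)),
        kappa = runif(1, 0, 0.5),
        cr_true = exp(runif(1, 0, log(30))),
        group = "amblyopic"
      )
      d <- sort(exp(runif(8, log(1), log(4096))))
      p <- stereo_percent_correct(obs, d, 80, 80)
      expect_true(all(diff(p) >= 0))
      # for a balanced observer, deeper dominant-eye decrements never help
      bal <- simulated_observer(obs$stereo, kappa = obs$kappa, cr_true = 1)
      pc <- stereo_percent_correct(bal, 100, seq(80, 10, by = -10), 80)
      expect_true(all(diff(pc) <= 0))
      # performance is maximal at the observer's balance point
      cd <- pmax(1, pmin(100, 80 / obs$cr_true))
      p_bal <- stereo_percent_correct(obs, 100, cd, 80)
      p_off <- stereo_percent_correct(
        obs, 100, pmax(1, pmin(100, c(cd * 1.5, cd / 1.5))), 80)
      expect_true(all(p_off <= p_bal + 1e-12))
    }
  })
})

test_that("letter-report probability is anchored at the balance point", {
  obs <- simulated_observer(cr_true = 10, sigma_cr = 0.3)
  expect_equal(cr_report_probability(obs, 10), 0.5)
  expect_equal(cr_report_probability(simulated_observer(cr_true = 1), 1), 0.5)
  # one sigma above the balance point on the log10 axis
  expect_equal(cr_report_probability(obs, 10^1.3), pnorm(1))
  # strictly increasing in the presented ratio
  r <- 10^seq(-1, 2, by = 0.25)
  expect_true(all(diff(cr_report_probability(obs, r)) > 0))
  expect_equal(cr_report_probability(obs, obs$cr_true), 0.5)
  expect_error(cr_report_probability(obs, -1), "positive")
})

test_that("simulated trials are Bernoulli draws from the model", {
  sup <- ideal_observer(threshold = 2, lambda = 0)
  withr::with_seed(1, {
    # far suprathreshold, lapse-free: always correct
    expect_true(all(replicate(50, simulate_trial(sup, 4096))))
  })
  # determinism under a fixed seed
  obs <- ideal_observer()
  s1 <- withr::with_seed(3, replicate(100, simulate_trial(obs, 40)))
  s2 <- withr::with_seed(3, replicate(100, simulate_trial(obs, 40)))
  expect_identical(s1, s2)
  # long-run frequency approaches the model probability (p = 0.625)
  ob0 <- ideal_observer(threshold = 40, lambda = 0)
  hits <- withr::with_seed(11, replicate(10000, simulate_trial(ob0, 40)))
  expect_equal(mean(hits), 0.625, tolerance = 0.015 / 0.625)
})

test_that("observer constructor enforces its invariants", {
  expect_error(psychometric_params(5, -1), "beta")
  expect_error(psychometric_params(5, 1, lambda = 0.2), "lambda")
  expect_error(simulated_observer(cr_true = 0.5), "cr_true")
  expect_error(simulated_observer(kappa = -0.1), "kappa")
  expect_error(simulated_observer(va_dominant = 2), "logMAR")
})
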