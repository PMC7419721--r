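test_that("correlations behave on exact and monotone data", {
  x <- 1:10
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  expect_equal(correlate(x, exp(x), "spearman")$estimate, 1)
  zed <- correlate(rep(1, 5), 1:5)
  expect_true(is.na(zed$estimate))
  expect_match(zed$note, "zero variance")
  expect_error(correlate(1:3, 1:4), "equal length")
})

test_that("Table 3 log-log correlation is reproduced from the fixture", {
  # regression value computed independently from the packaged per-subject
  # table; guards the fixture and the correlation surface together
  t3 <- load_fixture("table3")
  r <- correlate(log10(t3$baseline), log10(t3$cr), "pearson")
  expect_equal(r$estimate, 0.4773, tolerance = 1e-4)
})

test_that("multiple regression reports R2, F and per-coefficient tests", {
  withr::with_seed(2, {
    x1 <- rnorm(14); x2 <- rnorm(14)
    y <- 2 + 1.5 * x1 - 0.5 * x2
    fit <- suppressWarnings(fit_multiple_regression(y, data.frame(x1, x2)))
    expect_equal(fit$r_squared, 1)
    # df bookkeeping for a single predictor at n = 14
    y2 <- x1 + rnorm(14, 0, 0.3)
    f2 <- fit_multiple_regression(y2, data.frame(x1))
    expect_equal(f2$df, c(1, 12))
    expect_error(fit_multiple_regression(y, data.frame(x1, x1b = 2 * x1)),
                 "collinear")
  })
})

test_that("regression R2 is invariant to affine predictor rescaling", {
  withr::with_seed(3, {
    x1 <- rnorm(30); x2 <- rnorm(30)
    y <- x1 + 0.5 * x2 + rnorm(30, 0, 0.5)
    a <- fit_multiple_regression(y, data.frame(x1, x2))
    b <- fit_multiple_regression(y, data.frame(x1 = 10 * x1 - 3,
                                               x2 = 0.2 * x2 + 7))
    expect_equal(a$r_squared, b$r_squared)
    expect_equal(a$statistic, b$statistic)
  })
})

test_that("repeated-measures ANOVA handles degenerate and 2-condition cases", {
  Y <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)
  expect_equal(rm_anova_with_posthoc(Y)$anova$statistic, 0)
  withr::with_seed(4, {
    Y2 <- cbind(base = rnorm(10), treat = rnorm(10, 0.8))
    res <- rm_anova_with_posthoc(Y2)
    tt <- t.test(Y2[, 2], Y2[, 1], paired = TRUE)
    expect_equal(res$anova$statistic, unname(tt$statistic)^2)
    expect_equal(res$anova$p_value, tt$p.value)
  })
  expect_error(rm_anova_with_posthoc(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("RM-ANOVA with GG correction matches the multivariate-lm oracle", {
  skip_if_not_installed("car")
  withr::with_seed(6, {
    n <- 12; k <- 4
    subj <- rnorm(n, 0, 1)
    Y <- sapply(1:k, function(j) subj + rnorm(n, 0.3 * j, c(0.5, 1, 1.5, 1)[j]))
    colnames(Y) <- paste0("c", 1:k)
    res <- rm_anova_with_posthoc(Y)
    mlm <- lm(Y ~ 1)
    idata <- data.frame(cond = factor(paste0("c", 1:k)))
    av <- suppressWarnings(car::Anova(mlm, idata = idata, idesign = ~cond,
                                      type = "III"))
    sm <- summary(av, multivariate = FALSE)
    gg_eps <- sm$pval.adjustments["cond", "GG eps"]
    expect_equal(res$anova$epsilon, unname(gg_eps), tolerance = 1e-6)
    expect_equal(res$anova$p_value,
                 unname(sm$pval.adjustments["cond", "Pr(>F[GG])"]),
                 tolerance = 1e-6)
  })
})

test_that("GG epsilon stays within its theoretical bounds", {
  withr::with_seed(8, {
    for (i in 1:15) {
      n <- sample(6:15, 1); k <- sample(3:6, 1)
      Y <- matrix(rnorm(n * k), n, k) %*% diag(runif(k, 0.5, 2))
      res <- rm_anova_with_posthoc(Y)
      eps <- res$anova$epsilon
      expect_gte(eps, 1 / (k - 1)); expect_lte(eps, 1)
      expect_equal(res$anova$df, eps * c(k - 1, (n - 1) * (k - 1)))
      # Bonferroni adjustment never lowers a p value
      expect_true(all(res$posthoc$p_adj >= res$posthoc$p_raw - 1e-15))
      expect_true(all(res$posthoc$p_adj ==
                        pmin(1, (k - 1) * res$posthoc$p_raw)))
    }
  })
})

test_that("paired log t-test is scale invariant and flags degeneracy", {
  a <- c(100, 200, 400, 800); b <- c(60, 150, 390, 500)
  t1 <- paired_t_log(a, b)
  t2 <- paired_t_log(a * 3.7, b * 3.7)
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  expect_equal(t1$df, 3)
  same <- paired_t_log(a, a)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  halved <- paired_t_log(a, a / 2)
  expect_match(halved$note, "degenerate")
  expect_error(paired_t_log(a, c(-1, 1, 1, 1)), "positive")
})

test_that("Experiment 3 paired test on the printed table reproduces p = 0.005", {
  t3 <- load_fixture("table3")
  res <- paired_t_log(t3$baseline, t3$balanced_cr)
  expect_equal(res$df, 6)
  expect_equal(res$statistic, 4.3143, tolerance = 1e-4)
  expect_equal(round(res$p_value, 3), 0.005)
})

test_that("condition tables carry means, relative changes and flags", {
  withr::with_seed(10, {
    base <- rnorm(8, 100, 5)
    Y <- cbind(baseline = base, same = base + rnorm(8, 0, 0.1),
               worse = base * 3 + rnorm(8, 0, 5))
    out <- build_condition_table(Y)
    expect_equal(out$table$relative_change[1], 1)
    expect_false(out$table$significant[1])
    expect_false(out$table$significant[2])
    expect_true(out$table$significant[3])
    expect_equal(out$table$mean, unname(colMeans(Y)))
  })
  # printed-mean fixtures reproduce the published relative changes
  expect_identical(relative_change(1780, 40), 44.5)
  expect_identical(relative_change(9.84, 1.44), 6.8)
})
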