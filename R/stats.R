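new_stat_result <- function(kind, statistic, df, p_value, estimate = NULL,
                            r_squared = NULL, coefficients = NULL,
                            epsilon = NULL, note = NULL) {
  structure(
    list(kind = kind, statistic = statistic, df = df, p_value = p_value,
         estimate = estimate, r_squared = r_squared,
         coefficients = coefficients, epsilon = epsilon, note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result:%s> statistic = %.4g, p = %.4g\n",
              x$kind, x$statistic, x$p_value))
  invisible(x)
}

#' Correlation with a two-sided test
#'
#' Pearson for interval data, Spearman for ordinal data (e.g. BF
#' scores).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `"stat_result"` with `estimate` (r or rho), `statistic`,
#'   `df` (Pearson) and two-sided `p_value`; zero-variance input yields
#'   `NA` estimates with a `note`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    return(new_stat_result(method, NA_real_, NA_real_, NA_real_,
                           estimate = NA_real_,
                           note = "undefined: zero variance"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  df <- if (method == "pearson") unname(ct$parameter) else NULL
  new_stat_result(method, unname(ct$statistic), df, ct$p.value,
                  estimate = unname(ct$estimate))
}

#' Ordinary least squares multiple regression
#'
#' Fits `response ~ .` on the predictor data frame and reports the
#' overall F test, R squared, and per-coefficient estimates with
#' two-sided p values. Used to disentangle the contributions of
#' interocular acuity difference and suppression depth to (log) stereo
#' thresholds.
#'
#' @param response numeric vector (typically log10 thresholds).
#' @param predictors data frame of numeric predictors (e.g. `va_diff`,
#'   `log10_cr`).
#' @return a `"stat_result"` with `kind = "regression"`, `statistic`
#'   (overall F), `df` (c(df1, df2)), `p_value`, `r_squared` and a
#'   `coefficients` data frame.
#' @export
fit_multiple_regression <- function(response, predictors) {
  stopifnot(is.data.frame(predictors))
  n <- length(response)
  if (nrow(predictors) != n) stop("response/predictor length mismatch")
  if (n <= ncol(predictors) + 1)
    stop("need n greater than number of predictors + 1")
  X <- cbind(1, as.matrix(predictors))
  if (qr(X)$rank < ncol(X))
    stop("collinear design: predictors are linearly dependent")
  dat <- cbind(data.frame(.response = response), predictors)
  fit <- lm(.response ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  new_stat_result(
    "regression", unname(fstat[1]), unname(fstat[2:3]),
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r_squared = sm$r.squared,
    coefficients = coefs[, c("term", "estimate", "std_error", "t", "p")]
  )
}

# Greenhouse-Geisser epsilon from the k x k condition covariance matrix,
# via the double-centred covariance.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- cov(Y)
  rowm <- rowMeans(S); colm <- colMeans(S); gm <- mean(S)
  Sc <- S - outer(rowm, rep(1, k)) - outer(rep(1, k), colm) + gm
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (den == 0) return(1) # degenerate covariance (e.g. identical columns)
  max(1 / (k - 1), min(1, num / den))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#' and Bonferroni post hoc tests versus baseline
#'
#' Classical within-subject one-way ANOVA: the condition effect is
#' tested against the subject-by-condition interaction, with degrees of
#' freedom multiplied by the Greenhouse-Geisser epsilon to guard against
#' sphericity violations (epsilon estimated from the double-centred
#' condition covariance). Post hoc pairwise paired t-tests compare every
#' non-baseline condition with the baseline, with Bonferroni-adjusted p
#' values (`min(1, m * p)`); the significance flags use adjusted
#' p < 0.01.
#'
#' @param measurements numeric matrix or data frame, subjects in rows,
#'   conditions in columns; the first column is the baseline. Complete
#'   cases only (no imputation).
#' @param flag_alpha adjusted-p threshold for the versus-baseline flags.
#' @return a list with `anova` (a `"stat_result"` with fractional
#'   `df = epsilon * c(k-1, (n-1)(k-1))` and `epsilon`) and `posthoc`
#'   (data frame: condition, t, df, p_raw, p_adj, significant).
#' @export
rm_anova_with_posthoc <- function(measurements, flag_alpha = 0.01) {
  Y <- as.matrix(measurements)
  if (anyNA(Y)) stop("missing cells are not supported (no imputation)")
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2 || n < 3) stop("need >= 2 conditions and >= 3 subjects")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cond", seq_len(k))

  gm <- mean(Y)
  cond_m <- colMeans(Y); subj_m <- rowMeans(Y)
  ss_cond <- n * sum((cond_m - gm)^2)
  ss_subj <- k * sum((subj_m - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  F <- if (ms_err > 0) ms_cond / ms_err else if (ss_cond == 0) 0 else Inf
  eps <- gg_epsilon(Y)
  p <- if (is.finite(F)) pf(F, eps * df1, eps * df2, lower.tail = FALSE)
       else 0
  anova_res <- new_stat_result("rm_anova", F, c(eps * df1, eps * df2), p,
                               epsilon = eps)

  m <- k - 1
  posthoc <- do.call(rbind, lapply(seq_len(m) + 1L, function(j) {
    d <- Y[, j] - Y[, 1]
    if (sd(d) == 0) {
      data.frame(condition = colnames(Y)[j], t = NA_real_,
                 df = n - 1, p_raw = if (all(d == 0)) 1 else NA_real_,
                 p_adj = if (all(d == 0)) 1 else NA_real_,
                 significant = FALSE)
    } else {
      tt <- t.test(Y[, j], Y[, 1], paired = TRUE)
      p_adj <- min(1, m * tt$p.value)
      data.frame(condition = colnames(Y)[j], t = unname(tt$statistic),
                 df = unname(tt$parameter), p_raw = tt$p.value,
                 p_adj = p_adj, significant = p_adj < flag_alpha)
    }
  }))
  rownames(posthoc) <- NULL
  list(anova = anova_res, posthoc = posthoc)
}

#' Paired t-test on log10 thresholds
#'
#' Stereo thresholds are compared on a logarithmic axis: the paired t is
#' computed on `log10` of the two positive threshold vectors. The result
#' is invariant to multiplying both vectors by a common positive
#' constant.
#'
#' @param baseline,treated equal-length positive vectors (arcsec).
#' @return a `"stat_result"` with `statistic` (t), `df = n - 1` and
#'   two-sided `p_value`; constant log-differences are flagged
#'   degenerate (`note`) with `NA` statistics.
#' @examples
#' paired_t_log(c(100, 200, 400), c(50, 120, 210))
#' @export
paired_t_log <- function(baseline, treated) {
  if (length(baseline) != length(treated))
    stop("`baseline` and `treated` must have equal length")
  if (any(baseline <= 0) || any(treated <= 0))
    stop("thresholds must be positive")
  d <- log10(baseline) - log10(treated)
  if (sd(d) == 0) {
    if (all(d == 0)) # identical vectors: no effect, by convention t = 0
      return(new_stat_result("paired_t", 0, length(d) - 1, 1, estimate = 0))
    return(new_stat_result("paired_t", NA_real_, length(d) - 1, NA_real_,
                           estimate = mean(d),
                           note = "degenerate: constant log-difference"))
  }
  tt <- t.test(log10(baseline), log10(treated), paired = TRUE)
  new_stat_result("paired_t", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, estimate = mean(d))
}

#' Build a per-condition summary table with versus-baseline flags
#'
#' Summarises a subject-by-condition set of measurements the way group
#' tables in dichoptic degradation studies are laid out: per-condition
#' mean, SD, relative change from baseline (ratio of means, one
#' decimal), and a significance flag from the Bonferroni-corrected
#' paired comparisons of [rm_anova_with_posthoc()].
#'
#' @param measurements subject-by-condition matrix or data frame; first
#'   column is the baseline.
#' @param flag_alpha adjusted-p threshold for flags.
#' @return a list with `table` (data frame: condition, mean, sd,
#'   relative_change, significant) and `anova` (the full
#'   [rm_anova_with_posthoc()] result).
#' @export
build_condition_table <- function(measurements, flag_alpha = 0.01) {
  Y <- as.matrix(measurements)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cond", seq_len(ncol(Y)))
  if (ncol(Y) < 1) stop("need a baseline column")
  res <- rm_anova_with_posthoc(Y, flag_alpha = flag_alpha)
  means <- colMeans(Y); sds <- apply(Y, 2, sd)
  rel <- vapply(means, relative_change, numeric(1),
                baseline_mean = means[1])
  flags <- c(FALSE, res$posthoc$significant)
  tab <- data.frame(condition = colnames(Y), mean = unname(means),
                    sd = unname(sds), relative_change = unname(rel),
                    significant = flags)
  rownames(tab) <- NULL
  list(table = tab, anova = res)
}
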