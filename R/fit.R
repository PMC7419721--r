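# Negative log-likelihood of (alpha, beta) for binomial 4AFC data
# aggregated by disparity level; gamma fixed 0.25, lambda fixed.
stereo_nll <- function(alpha, beta, log2d, n, k, lambda) {
  p <- 0.25 + (0.75 - lambda) * pnorm((log2d - alpha) / beta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

aggregate_trials <- function(trials) {
  if (!all(c("disparity", "correct") %in% names(trials)))
    stop("`trials` must have `disparity` and `correct` columns")
  log2d <- log2(trials$disparity)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(trials)),
                                k = as.numeric(trials$correct)),
                          by = list(log2d = log2d), FUN = sum)
  agg[order(agg$log2d), ]
}

threshold_from_alpha <- function(alpha, beta, lambda, criterion = 0.625) {
  # disparity at which the fitted curve crosses the criterion
  2^(alpha + beta * qnorm((criterion - 0.25) / (0.75 - lambda)))
}

#' Fit a stereo threshold by maximum likelihood
#'
#' Pools the trials of a session (both interleaved staircases) into one
#' binomial likelihood for a cumulative normal on the log2 disparity
#' axis, with guess rate fixed at 0.25 (4AFC) and a fixed small lapse.
#' The reported threshold is the disparity at which the full fitted
#' curve crosses 62.5 percent correct -- the midpoint between chance and
#' perfect performance -- so the criterion holds exactly even with a
#' nonzero lapse.
#'
#' Optimisation is bounded L-BFGS-B from several starts (including the
#' winner of a coarse likelihood scan); a fit is `measurable` only if it
#' converged, the optimum is interior to the parameter bounds, the fit
#' beats the guess-rate-only (no stereopsis) model by a chi-square(2)
#' likelihood-ratio margin, and the criterion crossing lies within the
#' 1--4096 arcsec stimulus range.
#'
#' @param trials data frame with `disparity` (arcsec) and `correct`
#'   (logical) columns, e.g. `session$trials`; at least 20 trials over
#'   at least 2 distinct disparities.
#' @param lambda_fixed fixed lapse rate (default 0.01).
#' @param alpha_bounds,beta_bounds parameter box, log2 arcsec and
#'   octaves.
#' @param criterion percent-correct criterion (default 0.625).
#' @return an object of class `"threshold_estimate"`: `threshold`
#'   (arcsec, `NA` when not measurable), `alpha`, `beta`, `lambda_used`,
#'   `n_trials`, `log_likelihood`, `converged`, `measurable`.
#' @export
fit_stereo_threshold <- function(trials, lambda_fixed = 0.01,
                                 alpha_bounds = c(log2(0.5), log2(8192)),
                                 beta_bounds = c(0.1, 8),
                                 criterion = 0.625) {
  agg <- aggregate_trials(trials)
  n_trials <- sum(agg$n)
  if (n_trials < 20 || nrow(agg) < 2)
    stop("need at least 20 trials spanning at least 2 distinct disparities")

  nll <- function(par) stereo_nll(par[1], par[2], agg$log2d, agg$n, agg$k,
                                  lambda_fixed)
  # starts: response-weighted mean level and spread variations, plus the
  # winner of a coarse likelihood scan (guards against local optima on
  # staircase-shaped designs)
  a0 <- sum(agg$log2d * agg$n) / n_trials
  scan_a <- seq(alpha_bounds[1], alpha_bounds[2], by = 0.25)
  scan_b <- c(0.1, 0.3, 0.7, 1.5, 3)
  scan <- expand.grid(a = scan_a, b = scan_b)
  scan_nll <- vapply(seq_len(nrow(scan)),
                     function(i) nll(c(scan$a[i], scan$b[i])), numeric(1))
  sbest <- scan[which.min(scan_nll), ]
  # near the lower beta bound the curve is step-like and the likelihood
  # is spiky in alpha; profile alpha finely along that edge as well
  fine_a <- seq(min(agg$log2d) - 1, max(agg$log2d) + 1, by = 0.02)
  z <- outer(agg$log2d, fine_a, "-") / beta_bounds[1]
  pf_ <- pmin(pmax(0.25 + (0.75 - lambda_fixed) * pnorm(z), 1e-12), 1 - 1e-12)
  fine_nll <- -colSums(agg$k * log(pf_) + (agg$n - agg$k) * log(1 - pf_))
  starts <- list(c(a0, 1), c(a0, 2), c(a0 + 1, 0.5), c(a0 - 1, 1.5),
                 c(sbest$a, sbest$b),
                 c(fine_a[which.min(fine_nll)], beta_bounds[1]))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(alpha_bounds[1], beta_bounds[1]),
            upper = c(alpha_bounds[2], beta_bounds[2])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }

  if (is.null(best)) {
    return(new_threshold_estimate(NA, NA, NA, lambda_fixed, n_trials, NA,
                                  converged = FALSE, measurable = FALSE))
  }
  converged <- best$convergence == 0
  alpha <- best$par[1]; beta <- best$par[2]
  eps <- 1e-6
  interior <- alpha > alpha_bounds[1] + eps && alpha < alpha_bounds[2] - eps &&
    beta > beta_bounds[1] + eps && beta < beta_bounds[2] - eps
  thr <- threshold_from_alpha(alpha, beta, lambda_fixed, criterion)
  # evidence of stereopsis: the fitted curve must beat the guess-rate-only
  # model by a chi-square(2) likelihood-ratio margin, otherwise the data
  # are chance-like and no threshold is claimed
  ll_chance <- sum(agg$k * log(0.25) + (agg$n - agg$k) * log(0.75))
  informative <- 2 * (-best$value - ll_chance) > stats::qchisq(0.95, 2)
  measurable <- converged && interior && informative && thr >= 1 && thr <= 4096
  new_threshold_estimate(if (measurable) thr else NA, alpha, beta,
                         lambda_fixed, n_trials, -best$value,
                         converged = converged, measurable = measurable)
}

new_threshold_estimate <- function(threshold, alpha, beta, lambda, n_trials,
                                   log_likelihood, converged, measurable) {
  structure(
    list(threshold = threshold, alpha = alpha, beta = beta,
         lambda_used = lambda, n_trials = n_trials,
         log_likelihood = log_likelihood, converged = converged,
         measurable = measurable),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf(
      "<threshold_estimate> %.1f arcsec (alpha=%.2f, beta=%.2f, n=%d, logL=%.2f)\n",
      x$threshold, x$alpha, x$beta, x$n_trials, x$log_likelihood))
  } else {
    cat("<threshold_estimate> not measurable\n")
  }
  invisible(x)
}

#' Brute-force grid-search threshold fit (testing oracle)
#'
#' Exhaustive maximum-likelihood search over an (alpha, beta) grid,
#' independent of the gradient-based optimiser. Used to validate
#' [fit_stereo_threshold()] on small instances.
#'
#' @inheritParams fit_stereo_threshold
#' @param alpha_grid,beta_grid numeric grids; must be non-empty.
#' @return a `"threshold_estimate"`.
#' @export
fit_stereo_threshold_oracle <- function(trials, lambda_fixed = 0.01,
                                        alpha_grid = seq(log2(0.5), log2(8192),
                                                         by = 0.02),
                                        beta_grid = exp(seq(log(0.1), log(8),
                                                            length.out = 60)),
                                        criterion = 0.625) {
  if (length(alpha_grid) == 0 || length(beta_grid) == 0)
    stop("grids must be non-empty")
  agg <- aggregate_trials(trials)
  n_trials <- sum(agg$n)
  if (n_trials < 20 || nrow(agg) < 2)
    stop("need at least 20 trials spanning at least 2 distinct disparities")

  best_val <- Inf; best_a <- NA; best_b <- NA
  for (b in beta_grid) {
    # vectorise over alpha for speed
    z <- outer(agg$log2d, alpha_grid, "-") / b
    p <- 0.25 + (0.75 - lambda_fixed) * pnorm(z)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    nlls <- -colSums(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
    j <- which.min(nlls)
    if (nlls[j] < best_val) { best_val <- nlls[j]; best_a <- alpha_grid[j]; best_b <- b }
  }
  interior <- best_a > min(alpha_grid) && best_a < max(alpha_grid) &&
    best_b > min(beta_grid) && best_b < max(beta_grid)
  thr <- threshold_from_alpha(best_a, best_b, lambda_fixed, criterion)
  ll_chance <- sum(agg$k * log(0.25) + (agg$n - agg$k) * log(0.75))
  informative <- 2 * (-best_val - ll_chance) > stats::qchisq(0.95, 2)
  measurable <- interior && informative && thr >= 1 && thr <= 4096
  new_threshold_estimate(if (measurable) thr else NA, best_a, best_b,
                         lambda_fixed, n_trials, -best_val,
                         converged = TRUE, measurable = measurable)
}

#' Estimate the interocular dominance ratio from letter-report trials
#'
#' Maximum-likelihood cumulative-normal fit of the probability of
#' reporting the nondominant eye's letter against the log10 presented
#' contrast ratio. The dominance ratio CR is the presented ratio at which
#' either report is equally likely (the 50 percent point).
#'
#' @param letter_trials data frame with `presented_ratio` (> 0) and
#'   `reported_nondominant` (logical), e.g. from [run_cr_session()]; at
#'   least 20 trials over at least 2 distinct ratios.
#' @param m_bounds bounds for the balance point on the log10-ratio axis.
#' @param s_bounds bounds for the spread.
#' @return an object of class `"cr_estimate"`: `cr`, `sigma`,
#'   `log_likelihood`, `converged`.
#' @export
estimate_cr <- function(letter_trials, m_bounds = c(-2.5, 3),
                        s_bounds = c(0.01, 2)) {
  stopifnot(all(c("presented_ratio", "reported_nondominant") %in%
                  names(letter_trials)))
  if (any(letter_trials$presented_ratio <= 0))
    stop("presented ratios must be positive")
  lr <- log10(letter_trials$presented_ratio)
  y <- as.numeric(letter_trials$reported_nondominant)
  if (nrow(letter_trials) < 20 || length(unique(lr)) < 2)
    stop("need at least 20 trials spanning at least 2 distinct ratios")
  if (all(y == 1) || all(y == 0)) {
    return(structure(list(cr = NA, sigma = NA, log_likelihood = NA,
                          converged = FALSE), class = "cr_estimate"))
  }
  nll <- function(par) {
    p <- pnorm((lr - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  starts <- list(c(mean(lr), 0.3), c(mean(lr), 0.1), c(0, 0.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = c(m_bounds[1], s_bounds[1]),
            upper = c(m_bounds[2], s_bounds[2])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || best$convergence != 0) {
    return(structure(list(cr = NA, sigma = NA, log_likelihood = NA,
                          converged = FALSE), class = "cr_estimate"))
  }
  eps <- 1e-6
  interior <- best$par[1] > m_bounds[1] + eps && best$par[1] < m_bounds[2] - eps
  structure(
    list(cr = 10^best$par[1], sigma = best$par[2],
         log_likelihood = -best$value, converged = interior),
    class = "cr_estimate"
  )
}

#' @export
print.cr_estimate <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("<cr_estimate> CR = %.2f (sigma = %.2f)\n", x$cr, x$sigma))
  } else {
    cat("<cr_estimate> not converged\n")
  }
  invisible(x)
}
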