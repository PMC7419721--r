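#' Configuration for a simulated experiment replica
#'
#' Three experiment designs are supported:
#' \describe{
#'   \item{1}{amblyopic cohort: stereo threshold, CR and VA measured
#'     once per observer; correlation and multiple-regression analysis
#'     of the VA/suppression dissociation.}
#'   \item{2}{normal cohort: stereo thresholds under dominant-eye
#'     contrast decrements (baseline, 10, 20, 30, 40 percent) and
#'     VA/CR/stereo under the five Bangerter filter levels, with
#'     repeated-measures ANOVA and Bonferroni post hoc tests.}
#'   \item{3}{amblyopic subsample: stereo thresholds at equal contrast
#'     and with the dominant eye rebalanced by the measured CR, CR+25
#'     percent CR and CR-25 percent CR; paired t-test on log
#'     thresholds.}
#' }
#'
#' @param experiment 1, 2 or 3.
#' @param n cohort size (defaults: 21, 19, 7).
#' @param seed integer root seed; every random stage derives a named
#'   substream from it.
#' @param contrast_decrements experiment 2 contrast conditions, percent
#'   of the nondominant eye's 80 percent base (0 = baseline).
#' @param bangerter_labels experiment 2 filter conditions.
#' @param rebalance_variants experiment 3 contrast conditions.
#' @param session a [session_config()] for stereo sessions.
#' @param cr_trials trials per dichoptic-letter CR measurement.
#' @return an object of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment, n = NULL, seed = 1L,
                              contrast_decrements = c(0, 10, 20, 30, 40),
                              bangerter_labels = c("0.8", "0.6", "0.4",
                                                   "0.1", "<0.1"),
                              rebalance_variants = c("equal", "cr",
                                                     "cr_plus_25",
                                                     "cr_minus_25"),
                              session = session_config(),
                              cr_trials = 60L) {
  if (!experiment %in% 1:3) stop("`experiment` must be 1, 2 or 3")
  if (is.null(n)) n <- c(21L, 19L, 7L)[experiment]
  if (experiment == 2) {
    if (any(contrast_decrements < 0) || any(contrast_decrements >= 100) ||
        contrast_decrements[1] != 0)
      stop("invalid contrast conditions: first must be baseline (0), ",
           "decrements in [0, 100) percent")
    if (!all(bangerter_labels %in% c("0.8", "0.6", "0.4", "0.1", "<0.1")))
      stop("invalid Bangerter filter label in condition list")
  }
  if (experiment == 3) {
    if (!all(rebalance_variants %in% c("equal", "cr", "cr_plus_25",
                                       "cr_minus_25")) ||
        rebalance_variants[1] != "equal")
      stop("invalid rebalance variants: must start with \"equal\"")
  }
  structure(
    list(experiment = as.integer(experiment), n = as.integer(n),
         seed = as.integer(seed), contrast_decrements = contrast_decrements,
         bangerter_labels = bangerter_labels,
         rebalance_variants = rebalance_variants,
         session = session, cr_trials = as.integer(cr_trials)),
    class = "experiment_config"
  )
}

measure_threshold <- function(observer, config, seed, contrast_pair = c(80, 80)) {
  sess <- config$session
  sess$contrast_pair <- contrast_pair
  result <- run_stereo_session(observer, sess, seed = seed)
  est <- fit_stereo_threshold(result$trials)
  if (!est$measurable) {
    # a failed fit is retested once, as a lab would rerun a session whose
    # staircase data did not support a threshold
    result <- run_stereo_session(observer, sess,
                                 seed = substream_seed(seed, "retest"))
    est <- fit_stereo_threshold(result$trials)
  }
  list(session = result, estimate = est)
}

measure_cr <- function(observer, config, seed) {
  trials <- run_cr_session(observer, n_trials = config$cr_trials, seed = seed)
  estimate_cr(trials)
}

#' Run a simulated experiment replica end to end
#'
#' Samples a cohort, runs every measurement session through the
#' staircase engine and psychometric fits, applies the scoring rules,
#' and computes the experiment's statistics. All randomness derives
#' from `config$seed` through named substreams, so the same
#' configuration reproduces the identical results bundle.
#'
#' @param config an [experiment_config()].
#' @return a list of class `"experiment_result"`; components depend on
#'   the experiment (see Details in the package vignette) but always
#'   include `config`, `cohort`, a per-observer `measurements` data
#'   frame, and `stats`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  switch(config$experiment,
         run_experiment1(config),
         run_experiment2(config),
         run_experiment3(config))
}

run_experiment1 <- function(config) {
  cohort <- sample_cohort(amblyopic_cohort_spec(
    n = config$n, seed = substream_seed(config$seed, "cohort")))
  rows <- lapply(seq_along(cohort), function(i) {
    obs <- cohort[[i]]
    thr <- measure_threshold(obs, config,
                             substream_seed(config$seed, "stereo", i))
    cr <- measure_cr(obs, config, substream_seed(config$seed, "cr", i))
    data.frame(
      observer = i,
      va_diff = obs$va_nondominant - obs$va_dominant,
      cr_hat = cr$cr, cr_true = obs$cr_true,
      threshold = thr$estimate$threshold,
      measurable = thr$estimate$measurable
    )
  })
  meas <- do.call(rbind, rows)
  ok <- meas$measurable & !is.na(meas$cr_hat)
  stats <- list(
    cor_cr = correlate(log10(meas$threshold[ok]), log10(meas$cr_hat[ok]),
                       "pearson"),
    cor_va = correlate(log10(meas$threshold[ok]), meas$va_diff[ok],
                       "pearson"),
    regression = fit_multiple_regression(
      log10(meas$threshold[ok]),
      data.frame(va_diff = meas$va_diff[ok],
                 log10_cr = log10(meas$cr_hat[ok])))
  )
  structure(list(config = config, cohort = cohort, measurements = meas,
                 stats = stats),
            class = "experiment_result")
}

run_experiment2 <- function(config) {
  cohort <- sample_cohort(normal_cohort_spec(
    n = config$n, seed = substream_seed(config$seed, "cohort")))
  n <- config$n

  # contrast-attenuation arm: dominant eye at (1 - k/100) * 80 percent
  dec <- config$contrast_decrements
  thr_c <- matrix(NA_real_, n, length(dec),
                  dimnames = list(NULL, paste0(dec, "%")))
  for (i in seq_len(n)) {
    for (j in seq_along(dec)) {
      pair <- c(80 * (1 - dec[j] / 100), 80)
      m <- measure_threshold(cohort[[i]], config,
                             substream_seed(config$seed, "contrast",
                                            i * 1000 + j),
                             contrast_pair = pair)
      # censor unmeasurable runs at the stimulus ceiling, as a clinical
      # dataset would record "worse than the largest disparity"
      thr_c[i, j] <- if (m$estimate$measurable) m$estimate$threshold else 4096
    }
  }
  contrast_table <- build_condition_table(thr_c, flag_alpha = 0.01)
  contrast_anova <- rm_anova_with_posthoc(log10(thr_c), flag_alpha = 0.01)

  # Bangerter arm: baseline plus the filter conditions
  labs <- c("baseline", config$bangerter_labels)
  thr_b <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
  cr_b <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
  va_b <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(n)) {
    for (j in seq_along(labs)) {
      obs <- if (labs[j] == "baseline") cohort[[i]] else
        apply_bangerter(cohort[[i]], labs[j])
      m <- measure_threshold(obs, config,
                             substream_seed(config$seed, "bangerter",
                                            i * 1000 + j))
      thr_b[i, j] <- if (m$estimate$measurable) m$estimate$threshold else 4096
      cr <- measure_cr(obs, config,
                       substream_seed(config$seed, "bangerter_cr",
                                      i * 1000 + j))
      cr_b[i, j] <- if (isTRUE(cr$converged)) cr$cr else obs$cr_true
      va_b[i, j] <- obs$va_dominant - obs$va_nondominant
    }
  }
  bangerter_tables <- list(
    va = build_condition_table(abs(va_b), flag_alpha = 0.01),
    cr = build_condition_table(cr_b, flag_alpha = 0.01),
    stereo = build_condition_table(thr_b, flag_alpha = 0.01)
  )
  bangerter_stereo_anova <- rm_anova_with_posthoc(log10(thr_b),
                                                  flag_alpha = 0.01)

  structure(
    list(config = config, cohort = cohort,
         measurements = list(contrast = thr_c, bangerter_stereo = thr_b,
                             bangerter_cr = cr_b, bangerter_va = abs(va_b)),
         tables = c(list(contrast = contrast_table), bangerter_tables),
         stats = list(contrast_anova = contrast_anova,
                      bangerter_stereo_anova = bangerter_stereo_anova)),
    class = "experiment_result"
  )
}

run_experiment3 <- function(config) {
  cohort <- sample_cohort(amblyopic_cohort_spec(
    n = config$n, seed = substream_seed(config$seed, "cohort")))
  variants <- config$rebalance_variants
  thr <- matrix(NA_real_, config$n, length(variants),
                dimnames = list(NULL, variants))
  true_thr <- thr
  cr_hat <- numeric(config$n)
  for (i in seq_len(config$n)) {
    obs <- cohort[[i]]
    cr <- measure_cr(obs, config, substream_seed(config$seed, "cr", i))
    cr_hat[i] <- if (isTRUE(cr$converged)) max(1, cr$cr) else obs$cr_true
    for (j in seq_along(variants)) {
      cond <- rebalance_contrasts(cr_hat[i], variants[j])
      pair <- c(cond$contrast_dominant, cond$contrast_nondominant)
      m <- measure_threshold(obs, config,
                             substream_seed(config$seed, "rebalance",
                                            i * 1000 + j),
                             contrast_pair = pair)
      thr[i, j] <- if (m$estimate$measurable) m$estimate$threshold else 4096
      true_thr[i, j] <- true_stereo_threshold(
        obs, contrast_dominant = pair[1],
        contrast_nondominant = pair[2])$threshold
    }
  }
  stats <- list(
    paired_t = paired_t_log(thr[, "equal"], thr[, "cr"]),
    fraction_improved = mean(thr[, "cr"] <= thr[, "equal"]),
    fraction_improved_true = mean(true_thr[, "cr"] <= true_thr[, "equal"])
  )
  meas <- data.frame(observer = seq_len(config$n), cr_hat = cr_hat,
                     cr_true = vapply(cohort, `[[`, 0, "cr_true"))
  structure(
    list(config = config, cohort = cohort, measurements = meas,
         thresholds = thr, true_thresholds = true_thr, stats = stats),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> experiment %d, n = %d, seed = %d\n",
              x$config$experiment, x$config$n, x$config$seed))
  invisible(x)
}
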