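#' Adaptive staircase state
#'
#' One staircase tracking a stimulus level on the log2-arcsec disparity
#' axis. Two rules are supported: one-down/one-up (converging near 50
#' percent correct for a yes/no-like statistic) and two-down/one-up
#' (converging near 70.7 percent). A staircase terminates after 70 trials
#' or nine reversals, whichever comes first. Step size starts at
#' `step_initial` octaves and is halved at each of the first two
#' reversals, with a floor of `step_floor`.
#'
#' @param rule `"two_down_one_up"` or `"one_down_one_up"`.
#' @param start_level starting level in log2 arcsec (default
#'   `log2(1024)`, suprathreshold for all simulated observers).
#' @param step_initial initial step in octaves (> 0).
#' @param step_floor smallest step in octaves (> 0).
#' @param level_range length-2 clamp for the level, log2 arcsec.
#' @param max_trials,max_reversals termination limits.
#' @return an object of class `"staircase_state"`.
#' @export
staircase_state <- function(rule = c("two_down_one_up", "one_down_one_up"),
                            start_level = log2(1024),
                            step_initial = 2, step_floor = 0.5,
                            level_range = c(log2(1), log2(4096)),
                            max_trials = 70L, max_reversals = 9L) {
  rule <- match.arg(rule)
  if (step_initial <= 0 || step_floor <= 0)
    stop("step sizes must be > 0")
  if (start_level < level_range[1] || start_level > level_range[2])
    stop("`start_level` outside the level range")
  structure(
    list(rule = rule, level = start_level, step = step_initial,
         step_initial = step_initial, step_floor = step_floor,
         level_range = level_range,
         reversal_count = 0L, consecutive_correct = 0L, trial_count = 0L,
         last_direction = "none", done = FALSE,
         max_trials = as.integer(max_trials),
         max_reversals = as.integer(max_reversals),
         reversal_levels = numeric(0)),
    class = "staircase_state"
  )
}

#' Update a staircase with one trial outcome
#'
#' One-down/one-up: the level moves down one step after a correct
#' response and up after an incorrect one. Two-down/one-up: the level
#' moves down only after two consecutive correct responses (the counter
#' then resets) and up after any incorrect response. A reversal is
#' counted when the direction of actual level movement changes; moves
#' absorbed entirely by the range clamp do not count as movement. The
#' step is halved (down to the floor) at each of the first two reversals.
#' The staircase is done when it reaches its trial or reversal limit.
#'
#' @param state a [staircase_state()], not yet done.
#' @param correct logical trial outcome.
#' @return the updated `"staircase_state"`; `reversal_levels` records the
#'   level at which each reversal occurred (for convergence diagnostics).
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (state$done) stop("cannot update a finished staircase")
  state$trial_count <- state$trial_count + 1L

  move <- 0
  if (correct) {
    if (state$rule == "one_down_one_up") {
      move <- -1
    } else {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= 2L) {
        move <- -1
        state$consecutive_correct <- 0L
      }
    }
  } else {
    move <- 1
    state$consecutive_correct <- 0L
  }

  if (move != 0) {
    proposed <- state$level + move * state$step
    new_level <- min(max(proposed, state$level_range[1]), state$level_range[2])
    if (new_level != state$level) {
      direction <- if (new_level > state$level) "up" else "down"
      if (state$last_direction != "none" && direction != state$last_direction) {
        state$reversal_count <- state$reversal_count + 1L
        state$reversal_levels <- c(state$reversal_levels, state$level)
        if (state$reversal_count <= 2L)
          state$step <- max(state$step_floor, state$step / 2)
      }
      state$last_direction <- direction
      state$level <- new_level
    }
  }

  if (state$trial_count >= state$max_trials ||
      state$reversal_count >= state$max_reversals) {
    state$done <- TRUE
  }
  state
}

#' Select which interleaved staircase controls the next trial
#'
#' Uniform choice among the staircases that are not yet done, using R's
#' current random number stream.
#'
#' @param staircases named list of [staircase_state()] objects.
#' @return the name of the selected staircase.
#' @export
select_staircase <- function(staircases) {
  active <- names(staircases)[!vapply(staircases, `[[`, TRUE, "done")]
  if (length(active) == 0L) stop("all staircases are done; session over")
  if (length(active) == 1L) return(active)
  active[sample.int(length(active), 1L)]
}

#' Default stereo session configuration
#'
#' @param start_level start level, log2 arcsec.
#' @param step_initial,step_floor step schedule, octaves.
#' @param contrast_pair length-2 `c(dominant, nondominant)` percent.
#' @param max_trials,max_reversals per-staircase termination limits.
#' @return a list used by [run_stereo_session()].
#' @export
session_config <- function(start_level = log2(1024), step_initial = 2,
                           step_floor = 0.5, contrast_pair = c(80, 80),
                           max_trials = 70L, max_reversals = 9L) {
  list(start_level = start_level, step_initial = step_initial,
       step_floor = step_floor, contrast_pair = contrast_pair,
       max_trials = max_trials, max_reversals = max_reversals)
}

#' Run one stereo measurement session on a simulated observer
#'
#' A pair of interleaved staircases (one two-down/one-up, one
#' one-down/one-up) controls the trial-by-trial disparity. On each trial
#' one non-finished staircase is selected at random, the stimulus is
#' presented at its current level, the observer's 4AFC response is drawn
#' from the generative model, and the controlling staircase is updated.
#' The session ends when both staircases are done (at most 140 trials).
#'
#' @param observer a [simulated_observer()].
#' @param config a [session_config()].
#' @param seed integer seed; the full session replays bit-identically.
#' @return an object of class `"session_result"`: a list with `trials`
#'   (data frame: `trial_index`, `staircase_id`, `disparity`, `correct`,
#'   `sector_position`), `staircases` (final states), `seed`, `config`.
#' @export
run_stereo_session <- function(observer, config = session_config(), seed = 1L) {
  stopifnot(inherits(observer, "simulated_observer"))
  with_seed(as.integer(seed), {
    sc <- list(
      A = staircase_state("two_down_one_up", config$start_level,
                          config$step_initial, config$step_floor,
                          max_trials = config$max_trials,
                          max_reversals = config$max_reversals),
      B = staircase_state("one_down_one_up", config$start_level,
                          config$step_initial, config$step_floor,
                          max_trials = config$max_trials,
                          max_reversals = config$max_reversals)
    )
    max_total <- 2L * config$max_trials
    id <- character(max_total); disp <- numeric(max_total)
    corr <- logical(max_total); sect <- integer(max_total)
    i <- 0L
    while (!all(vapply(sc, `[[`, TRUE, "done"))) {
      i <- i + 1L
      s <- select_staircase(sc)
      d <- 2^sc[[s]]$level
      sector <- sample.int(4L, 1L)
      ok <- simulate_trial(observer, d, config$contrast_pair)
      sc[[s]] <- staircase_update(sc[[s]], ok)
      id[i] <- s; disp[i] <- d; corr[i] <- ok; sect[i] <- sector
    }
    trials <- data.frame(
      trial_index = seq_len(i), staircase_id = id[seq_len(i)],
      disparity = disp[seq_len(i)], correct = corr[seq_len(i)],
      sector_position = sect[seq_len(i)]
    )
    structure(
      list(trials = trials, staircases = sc, seed = as.integer(seed),
           config = config),
      class = "session_result"
    )
  })
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d trials (A: %d, B: %d), seed %d\n",
              nrow(x$trials), x$staircases$A$trial_count,
              x$staircases$B$trial_count, x$seed))
  invisible(x)
}

#' Run one dichoptic-letter contrast-ratio session
#'
#' A one-down/one-up staircase on the log10 presented contrast ratio
#' converges on the 50 percent balance point: after a nondominant-eye
#' report the presented ratio is lowered, after a dominant-eye report it
#' is raised. Sixty trials by default.
#'
#' @param observer a [simulated_observer()].
#' @param n_trials number of trials.
#' @param start_log_ratio starting log10 presented ratio.
#' @param step_initial,step_floor step schedule on the log10-ratio axis.
#' @param log_ratio_range clamp for the log10 presented ratio.
#' @param seed integer seed.
#' @return data frame with `presented_ratio` and `reported_nondominant`.
#' @export
run_cr_session <- function(observer, n_trials = 60L, start_log_ratio = 0,
                           step_initial = 0.3, step_floor = 0.075,
                           log_ratio_range = c(-2, 2.5), seed = 1L) {
  stopifnot(inherits(observer, "simulated_observer"))
  with_seed(as.integer(seed), {
    st <- staircase_state("one_down_one_up", start_level = start_log_ratio,
                          step_initial = step_initial, step_floor = step_floor,
                          level_range = log_ratio_range,
                          max_trials = n_trials, max_reversals = 10000L)
    ratio <- numeric(n_trials); rep_nd <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      r <- 10^st$level
      p <- cr_report_probability(observer, r)
      nd <- runif(1L) < p
      # reporting the nondominant letter plays the role of "correct":
      # the staircase then lowers the presented ratio toward balance
      st <- staircase_update(st, nd)
      ratio[i] <- r; rep_nd[i] <- nd
    }
    data.frame(presented_ratio = ratio, reported_nondominant = rep_nd)
  })
}
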