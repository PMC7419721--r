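const_step <- function(rule, level = log2(256), step = 1) {
  staircase_state(rule, start_level = level, step_initial = step,
                  step_floor = step)
}

test_that("two-down/one-up moves only after two consecutive corrects", {
  st <- const_step("two_down_one_up")
  L <- st$level
  st1 <- staircase_update(st, TRUE)
  expect_equal(st1$level, L) # single correct: counter armed, no move
  expect_equal(st1$consecutive_correct, 1L)
  st2 <- staircase_update(st1, TRUE)
  expect_equal(st2$level, L - 1) # second correct: down one step
  expect_equal(st2$consecutive_correct, 0L)
  st3 <- staircase_update(st2, FALSE)
  expect_equal(st3$level, L) # any incorrect: up
})

test_that("a hand-traced C,C,I,C,C sequence reproduces levels and reversals", {
  st <- const_step("two_down_one_up")
  L <- st$level
  seqn <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  presented <- numeric(5)
  for (i in seq_along(seqn)) {
    presented[i] <- st$level
    st <- staircase_update(st, seqn[i])
  }
  expect_equal(presented, c(L, L, L - 1, L, L))
  expect_equal(st$level, L - 1)
  expect_equal(st$reversal_count, 2L)
})

test_that("one-down/one-up moves on every trial", {
  st <- const_step("one_down_one_up")
  L <- st$level
  st <- staircase_update(st, TRUE)
  expect_equal(st$level, L - 1)
  st <- staircase_update(st, FALSE)
  expect_equal(st$level, L)
  expect_equal(st$reversal_count, 1L)
})

test_that("levels clamp to the stimulus range and clamped moves are not movement", {
  st <- staircase_state("one_down_one_up", start_level = log2(1),
                        step_initial = 2, step_floor = 2)
  st <- staircase_update(st, TRUE) # would go below the floor
  expect_equal(st$level, log2(1))
  expect_identical(st$last_direction, "none")
  expect_equal(st$reversal_count, 0L)
  st <- staircase_update(st, FALSE)
  expect_equal(st$level, log2(4))
  expect_identical(st$last_direction, "up")
})

test_that("staircases terminate at 70 trials or 9 reversals exactly", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      st <- staircase_state("two_down_one_up")
      while (!st$done) st <- staircase_update(st, runif(1) < 0.7)
      expect_true(st$trial_count <= 70 && st$reversal_count <= 9)
      expect_true(st$trial_count == 70 || st$reversal_count == 9)
    }
  })
  expect_error(staircase_update(structure(list(done = TRUE),
                                          class = "staircase_state"),
                                TRUE),
               "finished")
})

test_that("staircase selection is uniform over active staircases", {
  sc <- list(A = staircase_state("two_down_one_up"),
             B = staircase_state("one_down_one_up"))
  picks <- withr::with_seed(4, replicate(10000, select_staircase(sc)))
  expect_equal(mean(picks == "A"), 0.5, tolerance = 0.015 / 0.5)
  p1 <- withr::with_seed(8, replicate(50, select_staircase(sc)))
  p2 <- withr::with_seed(8, replicate(50, select_staircase(sc)))
  expect_identical(p1, p2)
  sc$A$done <- TRUE
  expect_identical(select_staircase(sc), "B")
  sc$B$done <- TRUE
  expect_error(select_staircase(sc), "done")
})

test_that("sessions replay bit-identically and respect the disparity range", {
  obs <- ideal_observer(threshold = 60, beta = 1.2, lambda = 0.01)
  s1 <- run_stereo_session(obs, session_config(), seed = 17)
  s2 <- run_stereo_session(obs, session_config(), seed = 17)
  expect_identical(s1, s2)
  expect_true(all(s1$trials$disparity >= 1 & s1$trials$disparity <= 4096))
  expect_lte(nrow(s1$trials), 140)
  expect_true(all(s1$trials$sector_position %in% 1:4))
  expect_true(all(diff(s1$trials$trial_index) == 1))
})

test_that("degenerate observers drive the staircases to the range limits", {
  # an observer who is always correct descends to the 1 arcsec floor
  perfect <- simulated_observer(psychometric_params(log2(1) - 20, 0.2,
                                                    lambda = 0))
  s <- run_stereo_session(perfect, session_config(), seed = 2)
  expect_equal(min(s$trials$disparity), 1)
  a_levels <- log2(s$trials$disparity[s$trials$staircase_id == "A"])
  expect_true(all(diff(a_levels) <= 0)) # monotone non-increasing
  expect_equal(s$staircases$A$trial_count, 70L)
  # an observer at chance with no luck rises to the 4096 arcsec ceiling
  blind <- simulated_observer(psychometric_params(log2(4096) + 40, 0.2,
                                                  lambda = 0.1, gamma = 0))
  s2 <- run_stereo_session(blind, session_config(), seed = 2)
  expect_equal(max(s2$trials$disparity), 4096)
})

test_that("the 2D1U staircase converges near its theoretical percent correct", {
  # the two-down/one-up rule tracks the ~70.7 percent correct point;
  # with lapses and finite runs the mean post-halving reversal level
  # should map to 66-75 percent correct on the true function
  obs <- ideal_observer(threshold = 40, beta = 1, lambda = 0)
  pcs <- vapply(1:500, function(i) {
    s <- run_stereo_session(obs, session_config(), seed = 40000 + i)
    rl <- s$staircases$A$reversal_levels
    if (length(rl) < 4) return(NA_real_)
    stereo_percent_correct(obs, pmin(4096, pmax(1, 2^mean(rl[-(1:2)]))))
  }, numeric(1))
  expect_gt(mean(pcs, na.rm = TRUE), 0.66)
  expect_lt(mean(pcs, na.rm = TRUE), 0.75)
})
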