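# Shared builders for test observers and sessions.

# Lapse-free observer with a 40 arcsec threshold and unit spread.
ideal_observer <- function(threshold = 40, beta = 1, lambda = 0,
                           kappa = 0.35, cr_true = 1, group = "normal") {
  simulated_observer(
    stereo = psychometric_params(log2(threshold), beta, lambda = lambda),
    kappa = kappa, cr_true = cr_true, group = group
  )
}

# Simulated 4AFC responses on a fixed disparity grid (no staircase).
grid_trials <- function(observer, disparities, n_per_level, seed = 1,
                        contrast_pair = c(80, 80)) {
  withr::with_seed(seed, {
    d <- rep(disparities, each = n_per_level)
    p <- stereo_percent_correct(observer, d, contrast_pair[1],
                                contrast_pair[2])
    data.frame(disparity = d, correct = runif(length(d)) < p)
  })
}
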