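#' Psychometric function parameters for the 4AFC stereo task
#'
#' Parameters of a cumulative-normal psychometric function on a base-2
#' logarithmic disparity axis: percent correct at disparity `d` arcsec is
#' `gamma + (1 - gamma - lambda) * pnorm((log2(d) - alpha) / beta)`.
#'
#' @param alpha threshold location on the log2-arcsec axis (so `2^alpha` is
#'   in arcsec).
#' @param beta spread of the cumulative normal, in octaves; must be > 0.
#' @param gamma guess rate; fixed at 0.25 for the four-alternative stereo
#'   task.
#' @param lambda lapse rate, in `[0, 0.1]`.
#' @return an object of class `"psychometric_params"`.
#' @examples
#' psychometric_params(alpha = log2(40), beta = 1)
#' @export
psychometric_params <- function(alpha, beta, gamma = 0.25, lambda = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive number (octaves)")
  if (lambda < 0 || lambda > 0.1)
    stop("`lambda` must lie in [0, 0.1]")
  if (gamma < 0 || gamma >= 1 || gamma + lambda >= 1)
    stop("`gamma` must lie in [0, 1) with gamma + lambda < 1")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
    class = "psychometric_params"
  )
}

#' Simulated observer for dichoptic stereo and letter-report tasks
#'
#' A generative observer defined by (i) a stereo psychometric function at
#' balanced interocular contrast, (ii) a contrast-imbalance sensitivity
#' `kappa`, (iii) an interocular dominance ratio `cr_true` governing both
#' the dichoptic-letter task and the internal attenuation of the
#' nondominant eye in the stereo task, and (iv) per-eye visual acuities.
#'
#' `alpha` of the stereo function is the threshold location measured at
#' equal presented contrast, i.e. it already includes whatever suppression
#' cost the observer incurs at 1:1 contrast. Rebalancing contrast toward
#' the observer's dominance ratio removes that cost (see
#' [stereo_percent_correct()]).
#'
#' @param stereo a [psychometric_params()] object (stereo task, equal
#'   presented contrast).
#' @param kappa contrast-imbalance sensitivity: log10 units of threshold
#'   elevation per 10 percent (of the stronger eye's contrast) effective
#'   interocular contrast decrement. Must be >= 0.
#' @param cr_true true interocular dominance (contrast) ratio, >= 1;
#'   1 means balanced eyes.
#' @param cr_stereo dominance ratio governing the stereo task: the
#'   presented nondominant:dominant contrast ratio at which the stereo
#'   system is balanced. Defaults to `cr_true` for amblyopic observers
#'   (cortical suppression gates stereo, so contrast rebalancing by the
#'   measured CR helps) and to 1 for normal observers (their small
#'   letter-task dominance does not penalise equal-contrast stereo, and
#'   any dominant-eye attenuation hurts).
#' @param sigma_cr spread of the dichoptic-letter report function on the
#'   log10 contrast-ratio axis.
#' @param va_dominant,va_nondominant logMAR acuities, each in
#'   `[-0.3, 1.5]`.
#' @param group `"normal"` or `"amblyopic"`.
#' @return an object of class `"simulated_observer"`.
#' @examples
#' obs <- simulated_observer(stereo = psychometric_params(log2(40), 1))
#' @export
simulated_observer <- function(stereo = psychometric_params(log2(40), 1),
                               kappa = 0.35,
                               cr_true = 1,
                               cr_stereo = NULL,
                               sigma_cr = 0.3,
                               va_dominant = 0,
                               va_nondominant = 0,
                               group = c("normal", "amblyopic")) {
  group <- match.arg(group)
  if (!inherits(stereo, "psychometric_params"))
    stop("`stereo` must be a psychometric_params object")
  if (cr_true < 1) stop("`cr_true` must be >= 1 (dominance convention)")
  if (is.null(cr_stereo))
    cr_stereo <- if (group == "amblyopic") cr_true else 1
  if (cr_stereo < 1) stop("`cr_stereo` must be >= 1 (dominance convention)")
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (sigma_cr <= 0) stop("`sigma_cr` must be > 0")
  for (va in c(va_dominant, va_nondominant))
    if (va < -0.3 || va > 1.5) stop("logMAR acuities must lie in [-0.3, 1.5]")
  structure(
    list(stereo = stereo, kappa = kappa, cr_true = cr_true,
         cr_stereo = cr_stereo, sigma_cr = sigma_cr,
         va_dominant = va_dominant, va_nondominant = va_nondominant,
         group = group),
    class = "simulated_observer"
  )
}

#' @export
print.simulated_observer <- function(x, ...) {
  cat(sprintf(
    "<simulated_observer> group=%s  threshold=%.1f arcsec  beta=%.2f oct\n",
    x$group, 2^x$stereo$alpha, x$stereo$beta))
  cat(sprintf("  cr_true=%.2f  kappa=%.3f  VA dom/nondom=%.2f/%.2f logMAR\n",
              x$cr_true, x$kappa, x$va_dominant, x$va_nondominant))
  invisible(x)
}

# Effective interocular imbalance in percent of the stronger eye's
# effective contrast. The nondominant eye's presented contrast is
# internally attenuated by cr_stereo before binocular combination.
effective_imbalance <- function(observer, contrast_dominant,
                                contrast_nondominant) {
  e_nd <- contrast_nondominant / observer$cr_stereo
  e_d <- contrast_dominant
  100 * (1 - pmin(e_nd, e_d) / pmax(e_nd, e_d))
}

check_disparity <- function(disparity) {
  if (any(!is.finite(disparity)) || any(disparity < 1) || any(disparity > 4096))
    stop("`disparity` must lie in [1, 4096] arcsec")
}

check_contrast <- function(contrast, what = "contrast") {
  if (any(!is.finite(contrast)) || any(contrast < 1) || any(contrast > 100))
    stop("`", what, "` must lie in [1, 100] percent")
}

#' Probability of a correct 4AFC stereo response
#'
#' Evaluates the observer's generative psychometric function at a given
#' disparity and presented contrast pair. Interocular contrast imbalance
#' shifts the threshold: the effective contrasts are the presented
#' contrasts after internal attenuation of the nondominant eye by
#' `cr_stereo`, and the threshold location is
#' `alpha + kappa * (log2(10) / 10) * (delta - delta_equal)` where `delta`
#' is the effective imbalance (percent of the stronger eye) at the
#' presented pair and `delta_equal` the imbalance at equal presented
#' contrast. For a stereo-balanced observer (`cr_stereo = 1`, the normal
#' default) this reduces to a pure dominant-eye-decrement penalty of
#' `kappa` log10 units per 10 percent decrement; for a suppressing
#' amblyopic observer, setting the presented ratio equal to the
#' dominance ratio removes the suppression cost and lowers the threshold
#' below its equal-contrast value.
#'
#' @param observer a [simulated_observer()].
#' @param disparity disparity in arcsec, in `[1, 4096]`; vectorised.
#' @param contrast_dominant,contrast_nondominant presented Michelson
#'   contrasts in percent, each in `[1, 100]`.
#' @return probability of a correct response (vector along `disparity`),
#'   nondecreasing in disparity.
#' @examples
#' obs <- simulated_observer(psychometric_params(log2(40), 1, lambda = 0))
#' stereo_percent_correct(obs, 40, 80, 80) # 0.625 at threshold
#' @export
stereo_percent_correct <- function(observer, disparity,
                                   contrast_dominant = 80,
                                   contrast_nondominant = 80) {
  stopifnot(inherits(observer, "simulated_observer"))
  check_disparity(disparity)
  check_contrast(contrast_dominant, "contrast_dominant")
  check_contrast(contrast_nondominant, "contrast_nondominant")
  p <- observer$stereo
  a_eff <- effective_alpha(observer, contrast_dominant, contrast_nondominant)
  p$gamma + (1 - p$gamma - p$lambda) * pnorm((log2(disparity) - a_eff) / p$beta)
}

# Threshold location (log2 arcsec) at a presented contrast pair.
# alpha is anchored at equal presented contrast, so the imbalance
# penalty is taken relative to the equal-contrast imbalance.
effective_alpha <- function(observer, contrast_dominant, contrast_nondominant) {
  delta <- effective_imbalance(observer, contrast_dominant, contrast_nondominant)
  delta_eq <- 100 * (1 - 1 / observer$cr_stereo)
  observer$stereo$alpha +
    observer$kappa * (log2(10) / 10) * (delta - delta_eq)
}

#' Model-implied stereo threshold at a presented contrast pair
#'
#' Inverts the generative psychometric function at the 62.5 percent
#' correct criterion (the midpoint between the 4AFC guess rate and
#' perfect performance).
#'
#' @inheritParams stereo_percent_correct
#' @param criterion percent-correct criterion defining the threshold.
#' @return a list with `threshold` (arcsec) and `measurable` (`TRUE` when
#'   the threshold lies within the 1--4096 arcsec stimulus range).
#' @export
true_stereo_threshold <- function(observer, contrast_dominant = 80,
                                  contrast_nondominant = 80,
                                  criterion = 0.625) {
  stopifnot(inherits(observer, "simulated_observer"))
  check_contrast(contrast_dominant, "contrast_dominant")
  check_contrast(contrast_nondominant, "contrast_nondominant")
  p <- observer$stereo
  z <- qnorm((criterion - p$gamma) / (1 - p$gamma - p$lambda))
  a_eff <- effective_alpha(observer, contrast_dominant, contrast_nondominant)
  thr <- 2^(a_eff + p$beta * z)
  list(threshold = thr, measurable = thr >= 1 && thr <= 4096)
}

#' Probability of reporting the nondominant eye's letter
#'
#' The dichoptic-letter task presents one letter to each eye and records
#' which is reported. The report probability follows a cumulative normal
#' on the log10 presented contrast ratio (nondominant over dominant),
#' centred on the observer's true dominance ratio: at
#' `presented_ratio = cr_true` either letter is equally likely.
#'
#' @param observer a [simulated_observer()].
#' @param presented_ratio contrast of the nondominant-eye letter over the
#'   dominant-eye letter; must be > 0. Vectorised.
#' @return probability the nondominant eye's letter is reported; strictly
#'   increasing in `presented_ratio`.
#' @examples
#' obs <- simulated_observer(cr_true = 10, sigma_cr = 0.3)
#' cr_report_probability(obs, 10) # 0.5 at the balance point
#' @export
cr_report_probability <- function(observer, presented_ratio) {
  stopifnot(inherits(observer, "simulated_observer"))
  if (any(!is.finite(presented_ratio)) || any(presented_ratio <= 0))
    stop("`presented_ratio` must be positive")
  pnorm((log10(presented_ratio) - log10(observer$cr_true)) / observer$sigma_cr)
}

#' Simulate a single 4AFC stereo trial
#'
#' Draws a Bernoulli correct/incorrect response from
#' [stereo_percent_correct()] using R's current random number stream.
#'
#' @inheritParams stereo_percent_correct
#' @param contrast_pair numeric length-2 vector
#'   `c(dominant, nondominant)` in percent.
#' @return logical: was the response correct?
#' @export
simulate_trial <- function(observer, disparity, contrast_pair = c(80, 80)) {
  stopifnot(length(contrast_pair) == 2L)
  p <- stereo_percent_correct(observer, disparity,
                              contrast_dominant = contrast_pair[1],
                              contrast_nondominant = contrast_pair[2])
  runif(1L) < p
}
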