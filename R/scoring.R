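#' Binocular-function (BF) score
#'
#' Ordinal rank of binocular function. When a graded clinical stereo
#' level (arcsec, 40--2000) was correctly identified, the score is its
#' log10 rounded to one decimal: 1.6 (40 arcsec) up to 3.3 (2000 arcsec).
#' When no stereoacuity is present, the score is 4 if the Worth 4 Dot
#' outcome indicates simultaneous perception / second-degree fusion, and
#' 5 if it indicates suppression.
#'
#' @param best_rpst_level best correctly identified stereo level in
#'   arcsec, or `NA` when no stereoacuity was demonstrated.
#' @param worth4dot `"fusion"`, `"suppression"`, or `"not_tested"`;
#'   required when `best_rpst_level` is `NA`.
#' @return numeric score: 1.6--3.3, 4, or 5.
#' @examples
#' bf_score(40)    # 1.6
#' bf_score(2000)  # 3.3
#' bf_score(NA, "suppression")  # 5
#' @export
bf_score <- function(best_rpst_level,
                     worth4dot = c("not_tested", "fusion", "suppression")) {
  worth4dot <- match.arg(worth4dot)
  if (!is.na(best_rpst_level)) {
    if (best_rpst_level < 40 || best_rpst_level > 2000)
      stop("`best_rpst_level` must lie in [40, 2000] arcsec")
    return(round(log10(best_rpst_level), 1))
  }
  switch(worth4dot,
         fusion = 4,
         suppression = 5,
         not_tested = stop(
           "a Worth 4 Dot outcome is required when no stereo level is present"))
}

#' Relative change from baseline
#'
#' Condition mean divided by baseline mean, rounded to one decimal
#' (round-half-to-even, as in R's `round`).
#'
#' @param condition_mean,baseline_mean group means; `baseline_mean` must
#'   be nonzero.
#' @return the one-decimal ratio.
#' @examples
#' relative_change(1780, 40) # 44.5
#' @export
relative_change <- function(condition_mean, baseline_mean) {
  if (any(baseline_mean == 0)) stop("baseline mean must be nonzero")
  round(condition_mean / baseline_mean, 1)
}

#' Contrast pair for a dominance-rebalancing condition
#'
#' The nondominant eye keeps the base contrast; the dominant eye's
#' contrast is divided by an effective ratio so that the presented
#' nondominant:dominant contrast ratio equals the depth of suppression:
#' `cr` for the exact rebalance, `1.25 * cr` and `0.75 * cr` for the
#' conditions bracketing it, and 1 for the equal-contrast baseline. The
#' dominant contrast is clamped to at least 1 percent (flagged).
#'
#' @param cr measured dominance ratio, >= 1.
#' @param variant `"equal"`, `"cr"`, `"cr_plus_25"`, or `"cr_minus_25"`.
#' @param base_contrast percent contrast of the nondominant eye
#'   (default 80).
#' @return an object of class `"contrast_condition"`: `variant`,
#'   `contrast_nondominant`, `contrast_dominant`, `cr_eff`, `clamped`.
#' @examples
#' rebalance_contrasts(4, "cr")          # dominant eye at 20 percent
#' rebalance_contrasts(4, "cr_plus_25")  # dominant eye at 16 percent
#' @export
rebalance_contrasts <- function(cr,
                                variant = c("equal", "cr", "cr_plus_25",
                                            "cr_minus_25"),
                                base_contrast = 80) {
  variant <- match.arg(variant)
  if (!is.numeric(cr) || cr < 1)
    stop("`cr` must be >= 1 (dominance convention)")
  if (base_contrast < 1 || base_contrast > 100)
    stop("`base_contrast` must lie in [1, 100] percent")
  cr_eff <- switch(variant,
                   equal = 1,
                   cr = cr,
                   cr_plus_25 = 1.25 * cr,
                   cr_minus_25 = 0.75 * cr)
  # the minus-25 variant of a balanced observer would raise the dominant
  # eye above base; the ratio floor of 1 keeps contrasts within range
  cr_eff <- max(cr_eff, 1)
  dominant <- base_contrast / cr_eff
  clamped <- dominant < 1
  if (clamped) dominant <- 1
  structure(
    list(variant = variant, contrast_nondominant = base_contrast,
         contrast_dominant = dominant, cr_eff = cr_eff, clamped = clamped),
    class = "contrast_condition"
  )
}
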