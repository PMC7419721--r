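---
title: "Simulating dichoptic stereoacuity experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dichoptic stereoacuity experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichoptr)
```

## The scientific problem

Amblyopia is usually described by the acuity loss in one eye, but the
accompanying loss of stereopsis correlates poorly with that acuity
deficit. A competing account holds that interocular suppression — the
cortical attenuation of the weaker eye's signal under binocular viewing
— is what limits stereoacuity, and that rebalancing the two eyes'
stimulus contrast in proportion to the measured depth of suppression
should restore some stereo function immediately. `dichoptr` provides a
complete, testable simulation of the psychophysics used to study this
question: adaptive-staircase threshold measurement on a 4AFC random-dot
stereo task, dichoptic-letter measurement of the suppression depth
(the contrast ratio, CR), phenomenological Bangerter-filter degradation,
CR-proportional contrast rebalancing, and the group statistics used to
summarise such experiments.

## The generative observer model

A simulated observer answers the 4AFC stereo task according to a
cumulative normal on the base-2 log disparity axis:

$$P(\text{correct} \mid d) = \gamma + (1 - \gamma - \lambda)\,
  \Phi\!\left(\frac{\log_2 d - \alpha_\text{eff}}{\beta}\right),$$

with guess rate $\gamma = 0.25$ (four alternatives), lapse rate
$\lambda$, spread $\beta$ in octaves, and threshold location
$\alpha_\text{eff}$ in log2 arcsec. The 62.5 %-correct point — midway
between chance and perfect — defines the threshold.

Interocular contrast imbalance shifts the threshold. Presented contrasts
$(c_\text{nd}, c_\text{d})$ are first mapped to *effective* contrasts by
attenuating the nondominant eye by the observer's stereo balance point
$\mathrm{CR}_s$: $e_\text{nd} = c_\text{nd}/\mathrm{CR}_s$,
$e_\text{d} = c_\text{d}$. The imbalance is the percentage shortfall of
the weaker effective eye,
$\Delta = 100\,(1 - \min(e)/\max(e))$, and

$$\alpha_\text{eff} = \alpha + \kappa\,\frac{\log_2 10}{10}
  \left(\Delta - \Delta_\text{equal}\right),$$

where $\Delta_\text{equal}$ is the imbalance at equal presented
contrast. Anchoring on $\Delta_\text{equal}$ makes $\alpha$ the
threshold *measured at equal contrast*, which is how baselines are
reported. The sensitivity $\kappa$ is in log10 threshold-elevation
units per 10 % imbalance.

Two balance points are deliberately distinct:

* `cr_true` governs the dichoptic-letter task. The probability of
  reporting the nondominant eye's letter is
  $\Phi\big((\log_{10}\rho - \log_{10}\mathrm{CR})/\sigma\big)$ in the
  presented ratio $\rho$; at $\rho = \mathrm{CR}$ either report is
  equally likely.
* `cr_stereo` governs the stereo task. It defaults to 1 for normal
  observers and to `cr_true` for amblyopic observers.

This split is forced by the data the model must reproduce jointly.
Normally-sighted adults show letter-task CRs around 1.45, yet attenuating
their dominant eye *elevates* stereo thresholds monotonically (about
0.35 log10 units per 10 % decrement); if their letter CR set the stereo
balance point, mild attenuation would instead improve them. In
amblyopes, conversely, rebalancing by the measured CR demonstrably
improves stereo thresholds, so there the suppression measured by the
letter task does gate stereo. The package's first model used a single
balance point; its own integration tests on the contrast-attenuation
replica exposed the contradiction, and the two-parameter form is the
minimal repair. With `cr_stereo = 1` the model reduces exactly to a
one-sided dominant-eye-decrement penalty.

For a balanced observer, "k % decrement" means the dominant eye is
presented at $(1 - k/100)$ of the 80 % nondominant base, and
$\Delta = k$ in percent-of-base units, so $\kappa = 0.35$ reproduces the
0.35 log10 per 10 % slope directly.

## Cohort generation

Cohorts are sampled with one root seed and per-observer substreams, so
cohorts are reproducible element-wise and extending a cohort never
perturbs existing members. Truncated distributions are drawn by inverse
CDF, so bounds hold for every draw.

**Normal observers** (`normal_cohort_spec()`): letter CR from a
truncated log-normal with mean 1.45, SD 0.33 on [1.0, 2.2]; baseline
thresholds log-normal with mean 40 arcsec, SD 14, on [15, 75];
interocular acuity differences truncated normal 0.02 ± 0.04 logMAR on
[0, 0.10]; $\kappa$ log-normal around 0.35.

**Amblyopic observers** (`amblyopic_cohort_spec()`): letter CR truncated
log-normal with mean 9.6, SD about 11, on [1.29, 40] — deep suppressors
are rare but present. The baseline threshold is generated *from* the
dominance ratio, $\log_{10} T = \log_{10} 40 + 1.2 \log_{10}
\mathrm{CR} + \mathcal N(0, 0.4)$, floored at 40 arcsec, so suppression
carries the threshold variance by construction; the acuity difference
(0.02–0.96 logMAR) is drawn independently of it. These choices make the
characteristic dissociation — thresholds track suppression, not acuity
— a property of the generator rather than an accident of sampling, and
they put roughly 20–30 % of amblyopes beyond the 4096 arcsec ceiling
(unmeasurable), matching the proportion seen clinically.
The rebalancing sensitivity $\kappa$ for amblyopes is log-normal around
0.03: per-observer values implied by published individual rebalancing
gains lie in 0.004–0.06, an order of magnitude below the normal
observers' external-contrast slope. Using 0.35 for amblyopes would
predict implausibly enormous gains for deep suppressors.

What the generator does *not* emulate: test–retest learning effects,
eccentric fixation, unstable alignment, response biases, or any optics
of Bangerter foils (their effects are applied phenomenologically as a VA
decrement, a CR multiplier and a stereo-threshold multiplier taken from
group mean changes). Passing tests therefore show that the analysis
pipeline recovers the structure this model generates — not that real
observers obey the model.

## Staircases

Disparity is controlled by a pair of interleaved staircases, one
two-down/one-up (tracking ~70.7 % correct) and one one-down/one-up; on
each trial one unfinished staircase is chosen uniformly at random. Each
staircase ends after 70 trials or nine reversals, whichever comes first.
Choices the procedure description leaves open, fixed here and
configurable:

* start level 1024 arcsec — suprathreshold for every simulated observer
  and inside the 1–4096 arcsec range;
* step 2 octaves, halved at each of the first two reversals, floor 0.5
  octaves;
* levels clamp to [1, 4096] arcsec; a move fully absorbed by the clamp
  is not counted as movement, so it cannot create a spurious reversal;
* the missing-sector position is drawn uniformly from the four
  alternatives per trial.

The dichoptic-letter CR task uses a one-down/one-up staircase on the
log10 presented ratio (60 trials, step 0.3 halving to 0.075), which
converges on the 50 % balance point.

## Psychometric fitting

Trials from both staircases are pooled into one binomial likelihood
(the procedure description does not separate them, and pooling uses all
140 trials). The cumulative normal is fitted by bounded maximum
likelihood (`optim`, L-BFGS-B) with $\gamma$ fixed at 0.25 and
$\lambda$ fixed at 0.01 — a free lapse is not identifiable from at most
140 staircase trials. The threshold is reported as the 62.5 % crossing
of the *full* fitted curve, not as $\alpha$, so the criterion holds
verbatim even with a nonzero lapse.

Numerical choices:

* bounds $\alpha \in [\log_2 0.5, \log_2 8192]$,
  $\beta \in [0.1, 8]$ octaves; an optimum on the boundary is not
  trusted (`measurable = FALSE`);
* multiple starts, including the winner of a coarse likelihood scan and
  a fine alpha-profile along the lower beta edge, where staircase data
  often produce spiky step-function optima;
* a fit is only `measurable` if it also beats the guess-rate-only
  (no stereopsis) model by a likelihood-ratio margin
  ($\chi^2_2$, 0.95) — chance-level data can otherwise acquire a
  spurious interior crossing by fitting noise — and if the crossing
  lies inside [1, 4096] arcsec;
* a grid-search oracle (`fit_stereo_threshold_oracle()`) provides an
  optimiser-independent check and is used only in tests.

In the experiment runners, a session whose fit is not measurable is
retested once with a fresh derived seed, as a laboratory would rerun a
failed measurement; a second failure is censored at the 4096 arcsec
ceiling.

## Scoring and rebalancing

`bf_score()` implements the ordinal binocular-function rank: log10 of
the best graded stereo level (1.6 at 40 arcsec to 3.3 at 2000 arcsec),
4 for fusion without stereo, 5 for suppression. `relative_change()` is
the condition/baseline ratio of group means at one decimal
(round-half-even, R's default, which reproduces every internally
consistent printed table cell). `rebalance_contrasts()` holds the
nondominant eye at the 80 % base and divides the dominant eye by the
effective ratio — CR, 1.25·CR or 0.75·CR. The "±25 %" bracketing is
read as scaling the ratio (1.25·CR), not adding 25 contrast points,
because the protocol describes attenuation *proportional* to CR.

## Statistics

The analysis layer mirrors the study's pipeline: Pearson/Spearman
correlations; OLS multiple regression of log10 threshold on acuity
difference and log10 CR (the log10 response is assumed, consistent with
log-scale threshold reporting); one-way repeated-measures ANOVA with
Greenhouse–Geisser-corrected fractional degrees of freedom (epsilon from
the double-centred condition covariance; implemented directly and
cross-checked in the test suite against `car::Anova`'s multivariate
route); Bonferroni-corrected paired comparisons of every condition
versus baseline (the family is versus-baseline, matching how the tables
star conditions, not all pairs), flagged at adjusted p < 0.01; and
paired t-tests on log10 thresholds, which are invariant to the log base
and to common rescaling. On the packaged individual rebalancing table
the paired test gives t(6) = 4.31, p = 0.005.

## Problem sizes and determinism

Simulation-based checks use 500 staircase sessions for the
two-down/one-up convergence property, 200 full sessions for parameter
recovery (median absolute log2 threshold error ≤ 0.5 octave), 500
synthetic cohorts of n = 21 for the dissociation property, and the
n = 7 rebalancing replica — sizes at which the Monte-Carlo error of
each summary is far below the acceptance band while a full run stays
fast. Every random stage derives a named 31-bit substream from a single
root seed (`substream_seed()`), so cohorts, sessions and whole
experiment bundles replay identically.

## Known limitations

* The observer model is phenomenological; `cr_stereo` is a device to
  reconcile the normal and amblyopic contrast-manipulation findings,
  not a mechanistic account of suppression.
* Bangerter effects ignore the optical physics of the foils
  (microbubble scatter, phase scrambling); only their group-level
  consequences are modelled.
* The imbalance penalty is linear in the percent shortfall; it is
  calibrated over the 0–40 % range used with normal observers and the
  modest amblyopic $\kappa$ keeps deep-suppressor predictions in a
  plausible range, but the linear form is an extrapolation.
* Rendering uses normalised luminance; mapping to cd/m² (display
  calibration) is out of scope.
* Inferential statistics from the human cohorts (specific r, R², F
  values) are reproduced only qualitatively on synthetic cohorts —
  per-subject raw data are not available apart from the packaged
  individual rebalancing table.
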