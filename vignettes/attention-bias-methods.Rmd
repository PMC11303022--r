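---
title: "Methods: preferential-looking attention-bias analysis with gazebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preferential-looking attention-bias analysis with gazebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazebias)
```

## The problem

In a two-stimulus preferential-looking experiment, a subject (here: a
bonobo tested at a touch-free eye tracker in its group setting, or a human
zoo visitor) sees two scenes side by side for 3 s — one emotional, one
neutral — after a centrally presented fixation video. Two complementary
attention-bias measures are derived from the gaze stream:

* **Sustained attention**: the proportional looking duration for the
  emotional scene,
  `PLD = TFD_emotional / (TFD_emotional + TFD_neutral)`,
  where TFD (total fixation duration) is the summed fixation time inside
  a scene's region of interest (ROI) during stimulus presentation.
  Values above 0.5 mean the emotional scene held gaze longer.
* **Immediate attention**: which scene receives the first fixation after
  onset, binarized from the two times-to-first-fixation (TTFF).

`gazebias` implements the full path from raw gaze samples to Bayesian
posterior summaries of these measures, plus a seeded synthetic-data
generator so that every stage can be validated without any recordings.

## Preprocessing

**Fixation detection.** Commercial fixation filters are closed source, so
the package uses a standard velocity-threshold (I-VT style) detector:
maximal runs of consecutive valid samples whose point-to-point velocity
stays below a threshold, broken by invalid samples and by inter-sample
gaps longer than a tolerance. Defaults: minimum duration 60 ms, velocity
threshold 3 px/ms, maximum gap 75 ms. At a 60 Hz sampling rate the gap
tolerance spans up to four missing frames; the velocity threshold is far
above the jitter of a stable fixation (a few px per frame) and far below
a between-ROI saccade (hundreds of px per frame), so detection is
insensitive to its exact value in this geometry. Centroids are
time-weighted (each sample weighted by half the interval to its
neighbours, so weights sum to the run duration). The detector is verified
against a brute-force segmentation oracle on randomized streams.

**Calibration-drift correction.** A degraded calibration shifts all gaze
of a session horizontally. Because fixation x-coordinates in a
two-stimulus display cluster at the two ROI centres, the offset is
estimated by k-means with k = 2 on the x-coordinates of the session's
stimulus-window fixations: each cluster centre is matched to the nearest
ROI centre-x and the correction is the mean of (ROI centre − cluster
centre). K-means is initialized deterministically from the 25% and 75%
quantiles, making the estimate a pure function of its inputs. The
correction is applied only when its magnitude reaches a threshold
(default 50 px, a config knob — roughly a tenth of a stimulus width —
so well-calibrated sessions are never touched). Sessions where both
clusters map to one ROI (the subject only ever looked at one side) are
flagged degenerate and left uncorrected. Across 200 synthetic sessions
with injected offsets of 60–200 px in either direction, the median
absolute estimation error is about 3 px (the validation requires ≤ 10 px).

**Trial metrics.** A fixation belongs to an ROI if its centroid lies in
the half-open rectangle (a centroid exactly on the shared boundary of the
two ROIs belongs to neither). TFDs are clipped to the stimulus window but
the unclipped per-ROI sums are retained, because trackers occasionally
report a final fixation running past stimulus offset and the validity
filter needs the tracker-reported total. TTFF is the onset-to-start
latency of the first fixation on the ROI, clamped at 0 for fixations
already ongoing at onset. A centre check records whether any pre-stimulus
fixation in the central ROI overlapped the final 500 ms before onset.

## Validity filters and looking statistics

Exclusion rules are applied **sequentially**; each trial is counted once,
under the first rule it triggers, and the ledger satisfies
`valid = total − Σ removed` by construction.

* Sustained (TFD) measure: (1) `no_gaze` — no fixation on either scene
  ROI; (2) `overrun` — the unclipped fixation total exceeds the 3 s
  presentation. The overrun test uses the *summed* unclipped total over
  both ROIs by default; a per-ROI variant is available
  (`overrun_rule = "per_roi"`) because either reading of
  "total fixation duration" is defensible, and retaining both lets the
  convention be audited.
* Immediate (TTFF) measure: in the primate protocol
  (`species_mode = "bonobo"`), (1) `center_fail_or_short` — the gaze was
  not on the fixation video in the final 500 ms before onset *or* the
  earliest scene latency is anticipatorily short (< 80 ms); both are
  symptoms of attention already being off-centre at onset, and they are
  pooled under one ledger reason. In the human protocol only the
  short-latency test applies. Then (2) `no_data`, and (3)
  `tie_or_single_roi` for exact latency ties. Ties are possible on a
  sampling grid and are excluded rather than randomized, keeping the
  measure deterministic; if only one ROI was ever fixated, that ROI wins.

Included sustained trials are scored with `PLD` and an attention weight,
`w = trial total looking / subject mean total looking`, the subject mean
taken over included trials only (weights are meaningless for trials that
are about to be discarded). Weights therefore average exactly 1 within
subject, and weighting the likelihood favours attentive trials.

## The Bayesian models

**Sustained attention** uses a weighted zero-one-inflated beta (ZOIB)
mixed regression, since PLD has genuine point masses at 0 and 1 (trials
where one scene was never fixated):

$$
f(y) \;=\;
\begin{cases}
  \mathrm{zoi}\,(1-\mathrm{coi}) & y = 0\\[2pt]
  \mathrm{zoi}\;\mathrm{coi} & y = 1\\[2pt]
  (1-\mathrm{zoi})\,
  \mathrm{Beta}\!\big(y;\,\mu\phi,\,(1-\mu)\phi\big) & 0 < y < 1
\end{cases}
$$

with logit-linear fixed effects on the beta mean $\mu$: the emotional
scene's side, and the interaction of scene species with emotion category.
All factors are sum coded (effects are deviations from the grand mean),
and the grouping structure is session nested within subject (random
intercepts for subject and for subject-session; no random slopes in this
model). The precision $\phi$, inflation probability `zoi` and
conditional-one probability `coi` are intercept-only submodels — the
package keeps them constant across conditions, a deliberate scope choice:
condition-dependent inflation can be emulated in the generator but is not
fitted. Trial weights enter as $\sum_i w_i \log f(y_i)$; integer weights
reproduce row-duplication exactly in the log posterior (a tested
invariant).

**Immediate attention** uses Bernoulli-logit mixed regression on the
first-fixation indicator with the same fixed effects; the grouping is a
cumulative-session counter nested in subject (primate protocol) or
subject (human protocol), with diagonal random slopes for emotion
category and species (`re_term("subject", ~ 0 + emotion_category +
species_on_scene)`); slope correlations are not modelled.

**Priors.** Normal(0, 1) on every location coefficient (including the
log/logit-scale intercepts of $\phi$, `zoi`, `coi`) and half-Student-t(3,
0, 2.5) on random-effect standard deviations, the truncation
renormalized. These weakly-informative choices regularize complete
separation in the logistic model (an all-ones outcome still yields a
finite posterior).

**Sampler.** Posterior draws come from an adaptive Metropolis-within-
Gibbs sampler written for dependency-free reproducibility, with blocks:

1. fixed-effect coefficients, componentwise random-walk updates;
2. the three auxiliary scalars (log $\phi$, logit `zoi`, logit `coi`);
3. random effects — all groups of a term column proposed jointly and
   accepted per group, valid because rows partition across groups;
4. a likelihood-invariant *location swap* (intercept += δ, all of a
   term's random intercepts −= δ), which resolves the ridge between the
   fixed intercept and the random-intercept mean when the group SD is
   small;
5. random-effect log-SDs (prior-only block), plus a joint *rescale* move
   (log-SD += δ, effects ×= e^δ; the Jacobian cancels the Gaussian
   prior's scale term) that escapes the funnel at SD ≈ 0;
6. Robbins–Monro step-size adaptation toward 0.44 acceptance during
   warmup only; step sizes are frozen afterwards so the retained chain is
   Markovian.

Proposals that push a parameter out of its domain (for instance an
inverse link saturating at exactly 0 or 1 in double precision) receive a
log-likelihood of −∞ and are rejected rather than raising errors.
Defaults follow the paradigm's analysis settings: 10,000 iterations with
2,000 warmup; the package runs 4 chains from dispersed random
initializations. All randomness derives from one integer seed.

**Summaries.** Each estimand is reported as the posterior median, the 89%
highest-density interval (the narrowest contiguous interval containing
89% of the draws — primary, with the equal-tailed quantile interval
emitted alongside for comparison), the probability of direction
`pd = max(P(θ > ref), P(θ < ref))` (ref 0 for coefficients and contrasts,
0.5 for response-scale proportions), and the split-chain Gelman–Rubin
diagnostic; any estimand with rhat > 1.05 is flagged, never silently
ignored. Multimodal samples make a contiguous HDI ambiguous; the interval
is still returned with a flag attribute. Condition estimates evaluate,
per draw, the response-scale mixture mean
$\mathrm{zoi}\cdot\mathrm{coi} + (1-\mathrm{zoi})\,\mu$ for a design cell
with random effects at zero; factors omitted from the cell are
marginalized by averaging the design row over their levels, and contrasts
are per-draw differences of two cells.

## The synthetic generator

`gen_config()` + `simulate_gaze()` emulate the study conditions the
analysis assumes: 3 s two-scene trials on a 1280 × 1024 px screen with
500 × 430 px stimuli; a −3000..0 ms centre-fixation segment mirroring the
3 s fixation video; five emotion categories crossed with two scene
species, the emotional side counterbalanced within session; per-trial
latent dwell proportions drawn from the same ZOIB model the analysis
fits, with logit-scale subject and session random intercepts;
constant-within-session horizontal calibration drift (magnitudes of order
±130–140 px are typical injections in the validation suite); missing-gaze
trials (default rate 0.097); final fixations overrunning stimulus offset
(default rate 0.01, unclipped totals around 4.6 s); and absent
pre-stimulus centre fixations (default rate 0.10). Default condition
means are 0.52 for conspecific-scene cells and 0.48 for
heterospecific-scene cells — a modest, realistic bias magnitude for this
paradigm — with subject/session intercept SDs of 0.20/0.10 on the logit
scale, beta precision 10, and total looking time per trial of mean 2.0 s
(SD 0.6), matching the attentiveness level of a primate tested without
restraint. Default design size is 4 subjects × 12 sessions × 10 trials.

The latent proportion is converted to alternating ROI dwells with
20–60 ms saccade gaps; any raw-gaze micro-structure with the right dwell
split serves the purpose, so the simplest is used. Dwell boundaries fall
on the 60 Hz sampling grid, and the ground-truth record stores the
*realized* per-scene dwell times measured as sample spans — exactly what
a fixation detector operating on those samples can recover — so
pipeline-recovered PLD matches the ground truth to machine precision on
clean trials. A planned dwell shorter than 100 ms is bumped up to 100 ms
(realized truth updated accordingly) so that every emitted dwell is
detectable. Drift is applied as a post-hoc coordinate shift: a drifted
and an undrifted run of one seed differ only by that shift.

What the generator does **not** emulate — and hence what passing tests do
not show about real recordings: realistic saccade kinematics and
undershoot, blinks and partial track loss inside a dwell (samples are
marked invalid only as whole-trial loss), vertical drift, pupilometry,
smooth pursuit, or stimulus-dependent salience structure within a scene.
Validation against this generator demonstrates correctness of the
pipeline's logic and calibration of its inference, not robustness to
every artifact of field eye-tracking.

## Validation design and problem sizes

The package's acceptance suite (mirrored by `scripts/acceptance.R`)
checks, at sizes chosen to exercise each property well:

* ledger accounting on four fixtures whose per-reason counts mirror the
  published exclusion tallies of the paradigm (1591- and 2821-trial
  designs);
* ZOIB density normalization to 1e−6 over a 54-point parameter grid
  (beta shapes ≥ 1, keeping the integrand bounded);
* weighted-likelihood ≡ row-duplication equality in log posterior
  (exact up to floating-point summation order, tolerance 1e−10);
* condition-mean recovery through the full pipeline at n = 2000 trials
  (8 subjects × 25 sessions × 10 trials; biases 0.55/0.50, zoi 0.05,
  φ 10): medians within 0.02 of truth and 89% HDIs covering it, with
  rhat < 1.05 at 2 × 2500 iterations. The recovery generator uses fixed
  condition means (no between-subject variance) so the target is the
  identifiable fixed effect;
* simulation-based interval calibration over 50 replicate generate→fit
  cycles at n = 240 trials: the 89% HDI covers the true condition mean
  in 80–96% of replicates. These replicates are likelihood-dominated
  (no between-subject variance): that is the regime in which credible
  intervals are expected to attain nominal frequentist coverage of a
  fixed truth. With few heterogeneous subjects (e.g. 4 at logit SD 0.1)
  the interval for the *population* mean is legitimately conservative —
  measured coverage 92–98% — because the subject-level mean is then
  prior-dominated; the interval still covers each replicate's
  realized-subject mean essentially always. This is a property of
  small-group hierarchical inference, not a defect of the sampler;
* drift recovery over 200 sessions and detector/oracle equivalence on
  randomized streams;
* byte-identical reruns of the end-to-end pipeline under one seed.

## Numerical choices and edge cases

* Half-open ROI rectangles; shared-boundary centroids belong to neither
  ROI.
* Coordinates: origin top-left, x rightward, y downward.
* `pld_emotion(0, 0)` is undefined and never produced: such trials are
  routed to `no_gaze` first.
* Exact TTFF ties are excluded (deterministic) rather than randomized.
* The human-protocol ledger can echo a pre-exclusion denominator so
  percentages can be reported against either the eligible or the
  collected trial count.
* `hdi()` on an m-out-of-n sorted window; `gb_rhat()` splits each chain
  in half and returns 1 for constant draws.
* Degenerate inputs tested: empty gaze logs (empty stream + warning),
  all-boundary responses (zoi → 1), complete separation (finite,
  prior-regularized posterior), single-cluster drift sessions (flagged).

## Known limitations

* φ, zoi and coi are intercept-only; condition-dependent precision or
  inflation is out of scope.
* Random slopes are diagonal (no correlation parameters), as is common
  for small-group designs where correlations are unidentifiable.
* The cumulative-session grouping is a running session counter per
  subject; with sequentially numbered sessions it coincides with the
  session index.
* The sampler is random-walk based; for much larger designs a
  gradient-based sampler would mix faster. At the sizes above, full
  default-length fits take a few minutes on one core.
* The quantile interval and the HDI can disagree for skewed posteriors
  (e.g. variance parameters near zero); the HDI is primary throughout.
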