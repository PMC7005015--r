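---
title: "Face scanning in dyadic interactions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Face scanning in dyadic interactions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscan)
```

## The problem

Head-mounted eye trackers record where a person looks during a live,
face-to-face conversation. Unlike screen-based eye tracking, the
conversational partner's face changes position, size and angle in every frame
of the scene video, so gaze cannot simply be pooled over time or across
participants. `dyadscan` implements the full analysis chain for such
recordings: fixation detection, face-region classification against a tracked
face quadrilateral, speech-conditioned region-of-interest (ROI) statistics,
and a spatially sensitive, data-driven comparison of gaze density maps on a
normalised face template using cluster-based Monte Carlo permutation
inference. Because real scene videos of this kind cannot be shared (they
identify the people in them), the package includes a first-class synthetic
cohort generator with known ground truth, and every stage is validated
against that ground truth or an independent oracle.

## Recording model and coordinate conventions

The pipeline assumes a 60 Hz gaze stream registered to a 24 fps scene camera
of 1280 x 960 px covering 60 x 46 degrees of visual angle. Conventions the
source instrumentation leaves unstated are fixed here once:

* scene pixels are 0-based, origin top-left, x rightward, y downward;
* gaze timestamps are numeric milliseconds; consecutive samples differ by
  exactly 1000/60 ms, so timestamps are doubles rather than integers;
* a gaze time `t` maps to scene frame `floor(t * 24 / 1000)`;
* pixel offsets convert to degrees by the per-axis linear scale
  60/1280 and 46/960 deg/px — a small-angle approximation, not a
  trigonometric camera model, because the dispersion threshold used
  downstream presupposes a fixed deg/px factor;
* one merged gaze point per sample is assumed (whether binocular data were
  averaged before fixation detection is not specified by the instrumentation;
  the pipeline consumes a single point).

All constants live in `analysis_config()`; every one can be overridden
programmatically or from a YAML file, and each override is smoke-tested to
change the behaviour it governs.

## Fixation detection (I-DT)

Fixations are detected with the classic dispersion-threshold algorithm: grow
a window while its dispersion stays within 0.5 degrees, emit it as a fixation
if it spans at least 50 ms, with the centroid as the arithmetic mean of the
member samples. Two choices deserve note:

* **Dispersion metric.** The vendor software the thresholds originate from
  does not publish its definition. The default here is the larger side of
  the window's bounding box in degrees (`dispersion_metric = "max"`), with
  the range-sum variant available as a config switch.
* **Validity runs split windows.** A single invalid sample (blink, track
  loss) terminates any open window; loss periods are excluded from valid
  time rather than bridged or interpolated, so proportional measures are
  computed against time where face looking could actually be asserted.

The detector is implemented as a compiled scan and is checked, interval for
interval, against a brute-force windowed reference implementation in the test
suite.

## Face box propagation and region classification

The partner's face is a convex quadrilateral per scene frame (vertices TL,
TR, BR, BL). Between detections the box is propagated by fitting a
least-squares similarity transform (translation, rotation, isotropic scale)
to tracked point correspondences — 4 degrees of freedom is robust at the
15-point minimum, and a full affine fit is available by config. Propagation
is refused, and re-detection demanded, when fewer than 15 correspondences
survive or 150 frames have elapsed since the last detection. The manual
moderation stage of the original semi-automatic procedure is replaced by this
re-detection contract plus a validation report listing the frames that
required attention.

Classification splits the quadrilateral at the midline joining the midpoints
of its left and right edges into an upper half (eye-region proxy) and a lower
half (mouth-region proxy). Tie-breaks are fixed and documented: points on the
midline count as upper; points on the box edge count as inside. A fixation is
classified at its temporal-midpoint frame; if no box exists within 6 frames
(250 ms, configurable), the fixation is unclassifiable and counts as data
loss. How fixations spanning a tracking gap should be handled is not
prescribed anywhere; the tolerance-then-flag rule is this package's own.

## Speech coding

Speaking periods start at the first audible-speech annotation and are cropped
at 30 s per task so participants contribute similar amounts of data. An
interruption ends coding at the instant just before it; if less than 20 s had
been coded, that first segment is discarded as insufficient and a single
second segment is coded from the second sentence after resumption (speakers
typically avert their gaze right at speech onset), again cropped at 30 s. No
third segment is ever coded. Listening periods are coded symmetrically from
the partner's speech events; when both partners are silent, no listening is
coded — listening is strictly the partner's coded speech. The "second
sentence" is an explicit annotation token: the pipeline consumes annotations,
mirroring manual coding, and does not infer sentence boundaries from audio.

## ROI statistics

Per participant x task x speech state, face fixation time is computed
proportional to valid total fixation time within the coded periods, and
upper-face time proportional to face time (undefined when face time is zero).
Fixations straddling a period boundary contribute only their within-period
portion, which preserves additivity. Cells with no classified fixation time
are flagged missing and removed listwise for the ANOVA, since the classical
mixed model needs complete within-subject data; no imputation is attempted.

The 2 (Group) x 2 (Speech) x 2 (Task) mixed ANOVA uses the type-III
repeated-measures formulation (via `car::Anova` with sum-to-zero contrasts),
matching the convention under which between- and within-effects are reported
with `F(1, N-2)`. All within factors have two levels, so sphericity holds
trivially and no correction is applied. Partial eta squared uses each
effect's own stratum error term. A hand sums-of-squares oracle verifies the
implementation on balanced designs.

Nonparametric follow-ups are implemented in-package with exact, tie-safe
null distributions — a dynamic program over signed midranks for the Wilcoxon
signed-rank test (up to 25 pairs) and full enumeration of rank splits for the
Mann-Whitney U (up to 10 per group) — because the base R routines decline
exact p-values under ties; they agree with the base routines on tie-free
data and with full enumeration oracles otherwise. Effect sizes follow the
`r = Z / sqrt(N)` convention. Spearman correlations use midranks with exact
p-values for small untied samples and the t approximation otherwise; group
trait comparisons default to the pooled two-sample t (df `n1 + n2 - 2`) with
Cohen's d.

## Density maps and cluster-based permutation inference

Face-directed fixations are remapped onto a normalised face template of
110 x 140 px at 0.1 deg/px, i.e. the 11 x 14 degree face area. The
quadrilateral-to-template map sends the four box vertices exactly to the four
template corners and interior points by inverse bilinear interpolation, which
reduces to an affine map for parallelogram boxes; the template resolution is
this package's convention (the original resolution is unpublished). Each
fixation deposits its duration (clipped to the coded periods) at its remapped
centroid; sample-level deposition is available behind a config flag. Maps are
collapsed across the two tasks and built separately for speaking and
listening.

Maps are smoothed with an isotropic Gaussian. "2 degrees width" is
interpreted as sigma = 2 degrees (a FWHM interpretation is a config switch).
Near the template boundary the truncated kernel is renormalised per source
pixel so smoothing conserves total mass exactly; maps are then normalised to
unit mass per participant so participants with more face time do not
dominate the group statistics (whether the original analysis normalised per
participant is unstated; this choice is explicit here).

Group inference uses pixelwise pooled-variance two-sample t statistics
(`df = n_A + n_B - 2`), thresholded two-sided at the cluster-forming p of
0.01. Supra-threshold clusters are connected components (8-neighbour by
default) formed separately for each sign; the cluster statistic is the pixel
count, with cluster mass available as a config hook. The null distribution of
the maximal cluster statistic is approximated by Monte Carlo over
whole-participant label exchanges (10,000 iterations by default), pooling the
maxima over both signs; a cluster's p-value is `(b + 1) / (m + 1)`, which
cannot be zero and is mildly conservative. Pixels with zero pooled variance
receive t = 0 when the means agree and an always-supra-threshold sentinel
otherwise. Neither Bonferroni nor random-field inference is offered: the
permutation approach is the method under study, and the alternatives are
out of scope by design.

One consequence of per-participant unit-mass normalisation is worth knowing
when reading results: a genuine localised group difference (say, at the
mouth) necessarily produces a compensating opposite-signed difference
elsewhere on the template, so a significant cluster of each sign is the
expected signature of a one-region effect. Localisation checks therefore look
at the cluster whose sign matches the direction of the effect.

## The synthetic cohort generator

The generator emulates the data model of a two-group, two-task dyadic study
(the stand-in for a 29 + 27 participant design is two groups of 28):

* **Gaze** is synthesised as alternating fixation/saccade segments, not
  noise, so the detector has true positives; saccades are 1-3 sample
  ballistic jumps. Fixation durations are lognormal with mean 300 ms and SD
  150 ms — literature-plausible values for conversation, since the source
  study reports no saccade or duration statistics of its own.
* **Fixation targets** come from a mixture of isotropic Gaussian components
  on the face template (eyes at 4.5 deg down the 14-degree template, centre
  at 7, mouth at 10.5, spreads about 1 degree) plus an off-face weight.
  Group A is mouth-biased, group B eye/centre-biased, emulating the style of
  contrast the method is designed to detect; both groups have off-face
  weight 0.45 while speaking and 0.12 while listening, which reproduces
  face-orienting medians in the 50-60% (speaking) and 85-90% (listening)
  range.
* **Head motion** moves the face box along sums of slow sinusoids (15-40 s
  periods) with rotation and scale proportional to the translation
  amplitude (30 px by default), keeping per-frame steps well under a pixel
  so true fixations stay within the dispersion threshold.
* **Track loss** comes in contiguous runs (geometric lengths, mean 8
  samples) whose stationary fraction matches the 8% loss rate, emulating
  smile-driven occlusion episodes rather than i.i.d. dropouts.
* **Traits** (AQ, LSAS) are drawn from group-specific normals truncated to
  instrument ranges, using the group means and SDs the emulated study
  reports; a latent eye-bias factor jitters each participant's mixture
  weights (log-scale SD 0.25, off-face logit SD 0.3) and can be linked to
  the traits to inject recoverable trait-gaze correlations.
* **Effects** are injected as an extra mixture component (e.g. weight 0.4
  over the mouth in one group), scaling everything else down so the mixture
  stays normalised. Magnitude 0.4 is the package's designed "clearly
  detectable" effect for recovery studies at 14 participants per group.

What the generator does *not* emulate: photorealistic appearance, saccade
dynamics beyond ballistic jumps, calibration drift, blinking-correlated gaze
shifts, partner-behaviour feedback loops, or task content. Passing tests
therefore demonstrate that the pipeline recovers what it is designed to
recover under a faithful data model — not that any particular empirical
claim about humans holds.

## Numerical choices and problem sizes

* Dispersion and duration comparisons use a 1e-9 tolerance so exact-boundary
  cases (a 50.000 ms window at 60 Hz) count as passing the threshold.
* Smoothing uses FFT convolution with a kernel truncated at 3 sigma and
  renormalised at the boundary; conservation holds to ~1e-9 relative.
* The inverse bilinear solve picks the quadratic root inside the unit
  square; for parallelograms the quadratic degenerates and the linear branch
  is used.
* Permutation streams are seeded from the config (`rng_seed`), and all
  generator functions take explicit seeds; same seed, same bytes.
* Validation studies run at sizes chosen to make their statistical claims
  with comfortable margins: the type-I-error study uses 200 null cohorts of
  14 vs 14 maps at 500 iterations each; effect-recovery studies use 50
  replicates (map-level at 14 per group for the spatial effect, full
  cohorts of 25 per group at 25 s per task for the speech effect, whose
  designed effect size is very large). The analysis drivers under
  `analysis/` run the full study conditions: 28 participants per group,
  70 s per task, 10,000 permutation iterations.

## Known limitations

* The pipeline consumes face quadrilaterals and point correspondences; it
  does not detect faces or compute optical flow from video.
* Listening coding requires partner speech annotations; silence is never
  coded as listening.
* The mixed ANOVA requires complete cells; there is deliberately no
  mixed-effects alternative or imputation.
* The cluster statistic is size (or mass); threshold-free variants are out
  of scope.
* Exact nonparametric p-values switch to normal approximations above the
  enumeration limits (25 pairs / 10 per group).
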