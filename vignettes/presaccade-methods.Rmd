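---
title: "Isolating pre-saccadic visually evoked MEG activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating pre-saccadic visually evoked MEG activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

When the eyes are about to move, visual neurons change their response
properties before the movement starts; some begin responding to stimuli that
will only fall into their receptive field after the saccade. At the scalp
level this predicts extra visually driven activity in the final ~100 ms
before saccade onset that cannot be explained by the saccade itself or by
the stimulus alone. `presaccade` implements a sensor-level analysis that
isolates that extra activity from MEG planar-gradiometer recordings.

The design has three conditions: trials with both a saccade and a visual
stimulus (Saccade+stimulus), trials with only a saccade (Saccade-only), and
fixation trials with only a stimulus (Stimulus-only). All analyses are
performed on saccade-locked combined planar gradients: epochs of
[-0.6, 0] s before saccade onset, averaged per gradiometer channel,
combined per site as the root-sum-of-squares of the orthogonal pair, and
baseline-corrected with the mean over [-0.6, -0.5) s. Because only trials
with saccade latencies in [0.150, 0.500] s are analysed, the baseline
window never contains stimulus-evoked activity. No temporal filtering is
applied before or after the combination.

## The condition-template model

For each participant and site, the Saccade+stimulus evoked gradient
$Y(t)$ is modelled as a weighted combination of the two single-condition
templates,

$$Y(t) = \beta_{sacc}\,X_{sacc}(t) + \beta_{stim}\,X_{stim}(t) +
\varepsilon(t),$$

fit by ordinary least squares over the time samples of the saccade-locked
window. There is no intercept: all three traces are baseline-corrected to
zero over the same window and the model contains exactly the two condition
regressors (an `intercept` flag exists for sensitivity analyses). The
residual $\varepsilon(t)$ is the activity unique to the conjunction of an
upcoming saccade and a visible stimulus — the signature of pre-saccadic
visual anticipation. Stimulus-only trials are pooled across all eight
stimulus feature combinations when forming the template.

Fixation trials have no saccade to lock to. Surrogate saccade onsets are
therefore drawn from Gaussian kernel density estimates of the observed
saccade latencies, fit per participant and per stimulus-feature cell
(orientation x spatial frequency x phase, 8 cells; cells with fewer than 5
latencies fall back to the participant's pooled distribution). For each of
`nDraws` (1000 at full scale) iterations every Stimulus-only trial is
relocked to its sampled onset, the evoked chain is recomputed, the model is
refit, and the per-site residual traces are reduced to their element-wise
median across draws — the median, rather than the mean, protects against
extreme draws.

Group inference uses a one-sample spatiotemporal cluster-permutation test
of the median residuals against zero (two-tailed, alpha = 0.05):
point-wise t values are thresholded at the parametric two-tailed critical
value (df = n - 1), suprathreshold points are clustered under spatial
adjacency (layout distance below the neighbour radius) x temporal
contiguity, cluster mass is the summed t, and the null distribution of the
maximum absolute mass is built from random participant sign-flips
(p = (1 + #{null >= observed}) / (1 + nPerm); exact enumeration is used for
small cohorts). Sites are highlighted when significant for at least
12.5 ms, with run span measured as (n - 1)/sfreq; the n/sfreq reading is
available behind a flag. Lateralization is assessed by left-minus-right
hemispheric medians (per participant and time point, cluster-tested over
time), by paired hemispheric t-tests on per-site summaries, and by
chi-square plus Bayes-factor tests on significant-sensor counts in the two
pre-saccadic windows ([-112, -50] ms and [-50, 0] ms; Bonferroni factor 2).
The Bayes factor compares independent Beta(1, 1) proportions against a
common proportion, computed by numerical integration of the binomial
marginal likelihoods; values below 1 favour the null.

## The synthetic-data generator

Because the original recordings are not required, every stage is validated
against a generator (`simulateSession()`) that emulates the study design:
416/208/208 trials of the three conditions, a 14-degree leftward saccade
from a fixation point 7 degrees right of the vertical midline, stimulus
features crossing orientation (-30/+30 deg), spatial frequency (0.33/1.33
cyc/deg) and phase (0/pi), and saccade latencies restricted to
[0.15, 0.5] s. Latencies follow a truncated log-normal (median ~230 ms,
right-skewed, as is typical for saccades) and are quantized to the
eye-tracker sample grid, as a sample-based detector would report them.

Sensor activity is specified directly at sensor level (no head model):
each component has a non-negative amplitude envelope, a spatial weight map
over sites, and a lateralization mode. Per site, the summed component
amplitude A(t) is split over the gradiometer pair as
(A cos theta, A sin theta) with a fixed per-site angle, so the
root-sum-of-squares recovers A(t) exactly at zero noise. Envelopes are
non-negative because the combined planar gradient is a magnitude; a signed
biphasic course would break that identity. Defaults: a gamma-shaped
saccade component peaking 30 ms after saccade onset (amplitude 5), a gamma
stimulus component peaking 120 ms after stimulus onset (amplitude 3,
right-lateralized for the left-hemifield stimulus — its weights are exactly
zero on left-hemisphere sites), and an optional "residual" component, a
half-Hanning ramp rising from 112 ms before saccade onset (amplitude 0 by
default; 1.5 — half the stimulus peak — in the injection experiments).
Inside Saccade+stimulus trials the saccade and stimulus templates are
scaled by the ground-truth weights (1.3, 0.7).

Noise is white Gaussian (sd 1) plus 1/f pink noise (sd 1) per channel and
sample, one independent pink realization per channel per trial; the pink
spectrum is produced by a 3-pole/3-zero spectral-shaping filter. Gaze
traces use minimum-jerk saccade profiles with main-sequence durations
(~2.2 ms/deg + 21 ms), fixation jitter, optional microsaccades on fixation
trials, and a re-fixation saccade in the inter-trial blanking period. The
photodiode is grey during fixation, white during the stimulus and black
between trials, which exercises the trinary conversion (four linearly
spaced boundary values including the extremes; an interior-boundaries
variant is selectable).

What the generator does **not** emulate: environmental interference (so no
Maxwell filtering is needed or implemented), head movement, blinks by
default, across-trial noise correlations, and any source-space structure.
Passing tests therefore certify the algorithmic chain, not robustness to
those real-world nuisances.

## Numerical and design choices

* **Saccade detection.** Velocity comes from Savitzky-Golay differentiation
  (order 2). The window is 14 ms: with the conventional 20 ms window the
  smoothing smears velocity backwards and onsets are biased ~3 ms early
  (median error 3 ms, maximum 5 ms against minimum-jerk ground truth);
  at 14 ms the median onset error is 0.4 ms and the maximum 3 ms at
  0.05 deg RMS jitter. The peak threshold iterates PT <- mean + 6 sd over
  sub-threshold samples from PT = 100 deg/s to a 1 deg/s tolerance; onsets
  and offsets walk outward from each peak to the first sample below
  0.7 PT. Events shorter than 10 ms are discarded, events separated by
  less than 40 ms are merged, and an amplitude of exactly 0.5 deg counts
  as a microsaccade ("larger than 0.5 deg" read exclusively). Invalid
  samples are padded by 50 ms and excluded.
* **Inclusion rules.** Saccade trials need exactly one saccade between
  stimulus onset and the second stimulus, an endpoint at least 4 deg past
  the vertical midline and no lower than 2 deg below the horizontal
  midline, and a latency in [0.150, 0.500] s — bounds read inclusively,
  with each rejection logged under the first violated rule so the boundary
  choice is auditable. Fixation trials must stay within 2 deg of fixation
  and show no microsaccade above 0.5 deg.
* **Artifact annotation.** Visual inspection is replaced by a reproducible
  annotator: a trial is rejected when any sample exceeds an absolute
  amplitude bound or deviates from the robust across-trial centre (per-cell
  median) by more than 6 per-channel robust standard deviations; an
  optional manual mask file can be OR-ed in.
* **Epoching.** Stimulus-locked epochs are cut at [-0.5, 1.5] s, line
  noise (50/100/150 Hz) attenuated with a least-squares DFT fit on the
  continuous data, and epochs downsampled to 500 Hz with a zero-phase
  64-tap FIR low-pass (cutoff 0.4 x target, unit DC gain). Indices are
  0-based with half-open [onset, offset) extents; the saccade-locked
  window keeps the onset sample as its last sample.
* **Surrogate resampling.** Silverman bandwidth with a 5 ms floor;
  out-of-support KDE mass handled by rejection, so every surrogate onset
  lies in [0.150, 0.500] s. Each iteration relocks, averages, combines and
  baselines exactly as the real conditions; per-iteration solutions are
  computed (rather than pooling draws) and reduced by the element-wise
  median. One master seed derives all per-participant and per-stage
  streams, so runs are bit-for-bit reproducible.
* **Cluster statistics.** The cluster-forming threshold is the parametric
  two-tailed critical t; the default neighbour radius gives ~6 neighbours
  per site on the 102-site layout; permutations default to 1000 (200 in
  the validation experiments). Degenerate proportion tables (no
  significant sensors anywhere) report a zero chi-square with p = 1.

## Known limitations, measured

Two biases are inherent to the published method and are pinned by tests
rather than hidden:

* **Rectification attenuation.** The combined planar gradient is a
  magnitude, so after baseline correction a weak component rides on a
  soft-threshold (y ~ sqrt(A^2 + 2 sigma^2)). The strong, aligned saccade
  component is recovered essentially unbiased, but the weak,
  latency-smeared stimulus template is compressed: its weight is
  attenuated on the order of tens of percent at realistic noise even with
  hundreds of trials. A dedicated test measures this attenuation; the OLS
  estimator itself is exactly unbiased at zero noise and under the linear
  model.
* **Surrogate smearing bias.** The kernel-smoothed surrogate template is
  slightly wider than the empirical latency smear in the
  Saccade+stimulus condition, so small systematic residuals exist even
  without any injected effect. They are consistent across participants,
  which is why a full-pipeline null cohort is not an exact type-I
  calibration of the cluster test; calibration is instead performed on
  null residual arrays, where the family-wise error lands inside the
  binomial interval around the nominal 0.05.

## Validation experiment scales

The test suite and `scripts/acceptance.R` run the validation studies at a
reduced scale chosen once: cohorts of 20 simulated participants on a
12-site layout with 40/20/20 trials per condition at 500 Hz and 200
surrogate draws for the injected-residual experiments (50 cohorts in the
test suite); 200 null cohorts of 8 x 16 x 301 residual arrays with 200
permutations for the type-I calibration; 500 simulated saccades of
1-14 deg for the detector study; and a 3-participant, 6-site pipeline run
executed twice for the determinism check. The `pipelineConfig("test")`
preset (8 participants, 16 sites, 60/30/30 trials, 50 draws, 200
permutations) mirrors the `"full"` preset (28 participants,
102 sites, 416/208/208 trials, 1000 draws, 1000 permutations) in every
analysis constant.

## A minimal run

```r
library(presaccade)
cfg <- pipelineConfig("test", seed = 1)
res <- runPipeline(cfg, "run")
makeReport("run")
clusterTable(res$clusterStats)
```

The run directory contains only plain-text artifacts (TSV + JSON) plus a
manifest of content hashes; rerunning with the same configuration verifies
the hashes and is a no-op, and any tampered artifact is reported by name.
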