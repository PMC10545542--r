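---
title: "swimcal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{swimcal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and rules, the tunable parameters and why their defaults are
what they are, what the synthetic generator does and does not emulate, and
the design choices made where the underlying analysis left them open.

## The experimental setting

Head-restrained larval zebrafish (~6 days post fertilization) swim in
discrete *bouts* — a beat-and-glide pattern of short active periods
separated by glides — recorded as a signed tail angle at 300 Hz while
neural activity is imaged with a genetically encoded calcium indicator at
10–16 Hz (single plane) or ~5.55 volumes/s (volumetric). Electrical
micro-stimulation of the mesencephalic locomotor region (MLR) elicits
graded forward swimming; the analysis quantifies how behavior and neural
recruitment change with stimulation and how single reticulospinal neurons
encode locomotor kinematics.

Throughout, positive tail angle means a deflection toward the animal's
left. This camera-side convention is arbitrary but must be fixed: the sign
of the largest bend assigns turn direction, so `left_turn` here means
"largest bend positive". All intervals are half-open `[start, end)` in
seconds with the time origin at the first behavior sample.

## Kinematic segmentation

**Bends.** The tracker-level step is re-implemented directly on the angle
trace: a 3-sample median filter, local extrema, a hysteresis threshold
(`min_bend_amp_deg`, default 5°) that suppresses sub-threshold ripple, and
a collapse of consecutive same-sign extrema to the largest one. The
collapse only applies while the trace stays above the hysteresis level
between the two extrema; if the tail relaxes to baseline in between, the
extrema belong to different movements and both survive. Without this
condition a large bend at the end of one bout can swallow the first bend
of the next.

**Bouts.** Maximal intervals where a 5-sample median envelope of |angle|
exceeds `motion_threshold_deg` (default 3°), merged across gaps shorter
than `min_quiet_s` (default 100 ms). The median envelope keeps isolated
noise samples from opening a bout; intervals that contain no qualifying
bend are dropped as noise blips. With stimulation metadata, a bout
starting inside a train is `evoked`; bouts within 60 s after a train end
are flagged `post_stim` and excluded from the spontaneous pool, because
their kinematics may still be affected by the stimulation.

**Cycles.** An oscillation is two consecutive opposite-sign bends. The
instantaneous tail-beat frequency of a cycle is the inverse of the
same-side bend spacing, `1/(t_i − t_{i−2})`; per-bend amplitude is |amp|;
the oscillation count is `floor(n_bends / 2)`.

**Bout classes.** Maximum absolute bend amplitude below 25° → forward;
25–60° → turn, side from the sign of the maximum-magnitude bend; above
60° → discarded (escape/struggle-like movements are not analyzed as
turns).

**Episodes.** Three rules, applied to a bout's bend sequence with the
25° gate (`episode_amp_threshold_deg`):

1. runs of sub-threshold bends with ≥ `min_forward_osc` (default 3) full
   oscillations are forward episodes;
2. a rare isolated supra-threshold bend — flanked by at least two
   sub-threshold oscillations on each side, and no denser than one per six
   sub-threshold oscillations (`rule2MaxPerOsc`) — does not split a
   forward episode;
3. runs of supra-threshold bends are struggle episodes, split where
   consecutive supra-threshold bends are more than `struggle_split_s`
   (default 100 ms) apart.

Sub-threshold runs too short for rule 1 are merged into the nearest
episode of the same bout (dropped if the bout has no episode). Episode
boundaries snap to bend times — the underlying definition is qualitative
("symmetric traces"), and bend times are the only landmarks the bend
representation preserves. Bends absorbed by rule 2 stay inside the episode
interval but are excluded from its kinematic accounting, so a forward
episode always reports a sub-25° maximum amplitude and ≥ 3 oscillations.
"Symmetry" of forward episodes is enforced only through the amplitude
gate; no left/right balance statistic is computed.

**Forward index.** Per stimulation trial,
`(n_forward − n_struggle) / n_total` over episodes starting inside the
train; per stimulation site, the median over trials with 10 Hz trains at
1–2 µA (other parameters mainly elicit struggles and would bias the site
summary). A site with no qualifying trial reports `NA`.

## Fluorescence preprocessing

Per ROI: corrected fluorescence `F = F_raw − 0.7 · F_neuropil`
(`neuropil_factor`), then `ΔF/F = (F − F0)/F0`. `F0` is the median of `F`
over a period of behavioral inactivity of at least `min_inactivity_s`
(default 3 s); the window is the final 3 s of the longest bout-free
stretch, i.e. as far from the preceding bout as the session allows, where
residual indicator decay (τ ≈ 1.8 s) is smallest. If no such stretch
exists the baseline falls back to the median of the lowest 10th percentile
of `F` (the volumetric-recording convention) with a warning. Noise σ is
the sample standard deviation of ΔF/F over the same window; every
recruitment threshold is expressed in units of this σ. Neuropil
subtraction precedes baseline selection (the listed order of the
preprocessing chain).

Optional smoothing is a centered 3-frame running average with
shrink-to-valid edges (a 2-frame mean at the first and last frame), or a
zero-phase first-order low-pass for display and regression. Artifact
frames are replaced by linear interpolation between the nearest good
frames for correlation-style analyses, but are *dropped* (not
interpolated) from encoding-model fits and permutations to avoid leaking
interpolated structure into the null.

**Spike inference.** ΔF/F is modeled as nonnegative spikes convolved with
`k(t) = exp(−t/1.8 s)`. On a uniform frame grid this kernel is a
first-order autoregression, so the innovation
`r[t] = ΔF/F[t] − φ·ΔF/F[t−1]`, `φ = exp(−Δt/τ)`, inverts it exactly;
rectifying at zero imposes nonnegativity and coincides with the
nonnegative least-squares solution whenever the data were generated by
the matched kernel (the tests verify this against a dense NNLS solver).
This is a deliberately minimal deconvolution: no sparsity prior, no
kernel fitting.

**ROI segmentation.** The correlation map assigns each pixel its Pearson
correlation with the mean trace of its eight neighbors. Regions grow from
the highest remaining map value above 0.3; a candidate neighbor joins
when its correlation with the running mean trace of the current region
exceeds a threshold rising linearly from 0.3 (nearest neighbor) to 0.35
at 3 µm from the seed (constant beyond). Growing against the running
region mean (rather than the seed pixel alone) was chosen for stability
of the admission statistic as the region grows; ties are broken
first-found in row-major order. Regions outside the somatic area gate
(9–28 µm²) are rejected whole — an oversized region keeps growing until
its correlated blob is exhausted before rejection, so fragments of a
too-large blob cannot re-seed a spurious acceptance — and rejected pixels
leave the seed pool. ROI traces are sums over member pixels.

## Recruitment statistics

A **pulse response** is a ΔF/F maximum in the 3 s after stimulation
exceeding the pre-stimulus baseline (mean over 1.5 s) plus 3σ, evaluated
on raw (unfiltered) ΔF/F because filtering lags transients. Reliability
across intensities: a ROI that never responds is `non_recruited`; one
that responds at every trial from the first intensity at which it
responds at all is `reliable` (that intensity is its threshold); anything
else is `unreliable`. The strictness is configurable (`maxFailures`,
default 0). The rising slope of a transient is
`(ΔF/F_peak − ΔF/F_onset)/(t_peak − t_onset)`; onset/peak annotation is
automated here (first frame above baseline + 1σ that keeps rising for two
frames; peak = argmax within 3 s) and outputs are flagged as automated
estimates rather than curated annotations.

**Episode-locked recruitment** takes the ΔF/F maximum from 0.5 s before
episode start to 2 s after episode end, minus the median over the 300 ms
before the start (residual decay from the previous episode); recruited
means ≥ 5σ. The per-ROI **forward activity index** is
`(A_f − A_s)/(A_f + A_s)` with `A_f`, `A_s` the means over forward and
struggle episodes of the per-episode corrected maxima, floored at zero so
the index stays in [−1, 1]. Where the two available phrasings of this
index differ (mean ΔF/F versus mean of per-episode maxima), the
average-of-maxima variant is implemented; the per-episode maxima it
averages are exposed so the other reading can be assembled if needed.
The **forward cluster** comes from agglomerative clustering (Ward
linkage, Euclidean distance on z-scored ΔF/F traces; k between 3 and 6,
default 4) — the distance and linkage are fixed here for reproducibility,
configurable — and is the cluster with the highest mean forward activity
index, with a warning if that mean is not positive.

## Motor regressors and encoding models

Per imaging frame interval `[t_i, t_{i+1})`: iTBA = max |angle| over the
behavior samples in the frame; iTBF = mean of cycle frequencies whose
cycle midpoint falls in the frame (0 if none). Rise indicators apply a
Heaviside step to the first difference of a 5-frame running mean. Vigor
is the sliding standard deviation of the tail angle over 50 ms. Each
series is convolved with `exp(−t/1.5 s)` (GCaMP6s-like; implemented as
the exact recursive filter), sampled at frame times (instantaneous value,
not a frame average), and z-scored. The kernel is not normalized to unit
sum — z-scoring removes the scale anyway. Correlation-based ROI classes:
motor-correlated = motor correlation above the per-fish 75th percentile;
vigor-correlated = motor correlation above stimulus correlation *and*
vigor correlation in the top quartile (the "25th top percentile" is read
as at-or-above the 75th percentile of vigor correlations).

The encoding model is ordinary least squares of ΔF/F on the four
regressors plus intercept. Significance is a one-sided permutation test:
the null preserves the trace's autocorrelation by circular time-shifts of
ΔF/F, with shifts drawn uniformly between `10τ` and `T − 10τ` (traces
shorter than `20τ` are rejected); per coefficient,
`p = (1 + #{α_null ≥ α_obs}) / (1 + n_perm)`, and a coefficient is
significant when positive with `p < 0.05`. The test is one-sided because
the significance rule itself requires a positive coefficient. The
original permutation scheme and count are not specified; circular shifts
with `n_perm = 999` (tests and the acceptance script use 199) are this
package's documented choice. No multiple-testing correction is applied
across neurons, matching the per-neuron rule; a Benjamini–Hochberg
adjustment can be applied downstream on the returned p-values. The
max-ΔF/F versus oscillation-count relation is a simple regression on
`ln(n_oscillations)`; the log transform tames the long right tail of
oscillation counts.

## Bout-type activity mapping

Rest spike rates are sampled at frames whose behavior interval stays
below `rest_epsilon_deg` (0.5°) and overlaps no bout. For each bout type,
spike rates from 200 ms before bout start to bout end are pooled across
bouts of that type (pooled, rather than per-bout tests aggregated — the
rates are compiled over all bouts of the same type) and compared to rest
with a one-sided Wilcoxon rank-sum test (`stats::wilcox.test`); active
means `P < 0.01`. Types with fewer than 3 bouts yield an undefined
marker, not an error. Groups: forward-component = active in forward and
both turn directions; left/right steering = active for that side but not
forward; mutually exclusive with forward-component precedence. Sessions
qualify with ≥ 50 bouts and at least one bout of each class.

## The synthetic generator

`synthBout` builds forward bouts as lightly damped sines (amplitude
< 25°, ≥ 3 oscillations, TBF 15–30 Hz), turns as one signed 25–60°
steering half-cycle followed by a forward component, and struggles as
large bends above 60° at 5–10 Hz (above 60° so the whole-bout classifier
discards them, as escape-like movements are in practice).
`scheduleBouts` draws TBF from a normal centered at 17 Hz (clipped to
15–30), amplitudes 8–22°, 3–8 oscillations — bout durations a few
hundred milliseconds — matching the descriptive scales of spontaneous
locomotion in this preparation. `synthSession` assembles a 300-Hz trace
with quiet gaps, optional Gaussian angle noise, stimulation trains and
seconds-long evoked forward episodes. `synthNeurons` draws per-archetype
drive (frequency coders, amplitude-rise coders, oscillation counters,
forward-component/steering, stimulation-reliable/unreliable, null),
convolves with `exp(−t/1.8 s)`, and assembles
`F = F0·(1 + ΔF/F) + 0.7·F_neuropil + noise`. All generator entry points
take an explicit seed and are bit-reproducible.

What the generator does *not* emulate: motion artifacts and slow drift,
Poisson shot noise by default (an additive Gaussian model is used; shot
noise changes variance scaling but not the rule logic), overlapping or
merged ROIs, kernel mismatch between generation and inference, and
behavioral variability beyond the parametric bout families. Closed-loop
tests passing therefore show the analysis chain is self-consistent and
correctly implements its rules at realistic scales — not that it is
robust to every artifact of real recordings.

## Numerical choices and problem sizes

Degenerate inputs error early and explicitly: empty traces, non-uniform
time grids, non-positive baselines, rank-deficient designs (the collinear
columns are named), all-masked traces, zero-variance regressors in the
log-oscillation fit. Zero-variance ΔF/F traces yield `NA` correlations
and are excluded downstream rather than erroring. Ties in ROI growing are
broken in row-major order; the rank-sum test uses the exact distribution
or the tie-corrected normal approximation as appropriate to sample size
(the `stats::wilcox.test` default).

The validation suite exercises: 1,000 generated bouts (noise-free and at
σ = 1° angle noise) for classification/episode agreement; 500 random
episode multisets for the forward-index identity; 200 planted
reliability archetypes plus 1,000 null traces for the 3σ response rule;
200 planted and 500 null neurons at ~3,000 frames with 199 permutations
for encoding power and type-I error; 50 noise-free transient traces for
spike inference; 1,000 null neurons for the rank-sum type-I error; and
two planted 12-µm² disks for ROI recovery. These sizes were chosen so
binomial error on the estimated rates is small relative to the margins
being checked while the whole suite stays desk-scale.

## Known limitations

* Spike inference is exact only under the matched exponential kernel;
  real indicators have rise times and nonlinearities it ignores.
* The automated onset detector replaces human curation of transient
  onsets; its 1σ sustained-rise criterion is a convention, and rising
  slopes inherit its onset placement.
* Episode "symmetry" is amplitude-gated only.
* The permutation null assumes the trace is long relative to the
  indicator decay (enforced at 20τ) and approximately stationary.
* Behavior/imaging alignment is by shared trigger offset in the config;
  there is no data-driven clock alignment.
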