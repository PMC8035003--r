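---
title: "Measuring pulse rate variability by two-period time synchronous averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pulse rate variability by two-period time synchronous averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsaprv)
```

## The idea

Time synchronous averaging (TSA) recovers a clean waveform from a noisy
quasi-periodic signal by aligning every repetition at a fiducial landmark
and averaging; independent noise shrinks as $1/\sqrt{N}$.  Applied to a
radial-artery pulse recording in the classic way — one period per
repetition — TSA yields a high-quality single-period pulse template but
destroys all rhythm information.

`tsaprv` averages windows that span *two adjacent periods* instead.  Every
detected period is expanded by 50% of its own length on both sides, the
windows are aligned at the point of maximum first derivative of their core
period (the steep systolic upstroke, the pulse-wave analogue of the ECG R
peak), zero-filled to a common frame, and averaged:

$$X_a = \frac{1}{N}\sum_{i=1}^{N} X_i .$$

The first period of $X_a$ is sharp, because every window is aligned on its
own core upstroke.  The *second* period is smeared in proportion to the
variability of the cycle durations: if every cycle had the same length the
next upstroke would fall at the same offset in every window.  The distance
between the two ascending limbs of $X_a$ — the first-period upstroke
$X_f$ and the equally long stretch $X_s$ starting at the minimum before
the second-period maximum — is therefore a measure of pulse rate
variability (PRV) that never requires estimating a beat-to-beat interval
series.  Three candidate index formulas are provided:

$$D_e = \sqrt{\textstyle\sum_i (x_{fi}-x_{si})^2},\qquad
  D_m = \textstyle\sum_i |x_{fi}-x_{si}|,\qquad
  D_c = \frac{\sum_i x_{fi}x_{si}}{\sqrt{\sum_i x_{fi}^2}\sqrt{\sum_i x_{si}^2}} .$$

$D_c$ is written exactly as conventionally printed for a "cosine
distance", although it is a cosine *similarity*: identical limbs give 1.
Atrial fibrillation (AF), whose hallmark is irregularly irregular cycle
durations, is called when $D_e$ strictly exceeds a decision threshold
(default 2.1, in device-native amplitude-distance units).

Key physiological assumption: within an individual, systolic duration and
shape are nearly constant — cycle-length changes are absorbed almost
entirely by diastole.  This is what makes averaging *without any time
rescaling* meaningful and what makes the maximum-derivative point (rapid
ventricular ejection) the most interference-resistant fiducial.

## The pipeline and its parameters

1. **Segmentation** (`segment_at_threshold`, `select_threshold`).  The
   forward first difference scaled by the sampling rate (left-aligned; an
   optional moving-average smoother is off by default) is normalized by its
   global maximum.  Upward crossings of a threshold mark the systolic
   spikes; the cut point for each crossing is the nearest preceding sample
   where the derivative turns from non-positive to positive — the diastolic
   foot.  Crossings with no such turning point within one median
   inter-crossing interval are discarded.  Nine trial thresholds
   (0.1–0.9) are tried and the one producing the most quality-passing
   segments wins, ties going to the smallest threshold for determinism.
   Thresholds are interpreted as fractions of the global derivative
   maximum; that is the only reading under which a universal 0.1–0.9 grid
   makes sense.

2. **Quality screening** (`assess_quality`).  The published pipeline uses a
   trained per-beat logistic quality classifier whose coefficients are not
   public; `tsaprv` ships a pluggable strategy interface whose default is a
   rule-based screen: duration 0.3–2 s *and* at least 70% of the cohort's
   75th-percentile segment duration; amplitude range within 0.3–3 times the
   cohort median; boundaries in the lowest 20% of the segment's range
   (periods run foot to foot); a cap of 50 on the max-to-median
   absolute-slope ratio (spikes); and coherent slope directions among
   significant slopes (noise flips incoherently).  The duration-consistency
   and foot-boundary rules exist because a fragment of a cycle split at the
   dicrotic wave must not be allowed to out-count a clean segmentation
   during threshold selection — without them a split threshold can
   occasionally "win" and collapse the averaging frame.  A custom function
   or external model can be supplied via `prv_config(quality_model = )`.

3. **Expansion** (`expand_segments`).  Each normal segment of length $L$
   is widened by `round(0.5 * L)` samples per side (round half away from
   zero); windows that would leave the recording are dropped.  Neighbouring
   samples are used regardless of the neighbouring segments' own quality
   labels.  All coordinates are half-open intervals.

4. **Averaging** (`align_and_average`).  The common frame spans the maximum
   left and right extents around the fiducial; shorter windows are padded
   with exact zeros and the denominator is $N$ everywhere — the literal
   ensemble mean above.  The per-sample count of contributing windows is
   retained on the result.

5. **Limb extraction** (`extract_limbs`).  By default the frame is first
   trimmed to the region covered by *all* windows.  In the zero-filled
   tails the mean is dragged toward zero by the missing windows, and since
   the limb anchors are global minima over half-frames, an untrimmed frame
   can hand the first-limb anchor to a padding artefact rather than the
   diastolic foot.  Trimming costs only the few samples where coverage is
   partial (window extents differ by at most the cycle-duration jitter) and
   makes the anchors depend on the waveform alone; `trim = "none"` restores
   the full frame.  Halves split at `floor(len/2)`; tied extrema resolve to
   the earliest index.  If the smeared second peak runs off the trimmed
   frame (extreme jitter relative to the cycle length) the extraction
   raises a "degenerate second limb" error; cohort drivers record `NA` for
   such recordings rather than aborting (`compute_indexes(on_error =
   "na")`).

The decision threshold 2.1 deserves a caveat: $D_e$ scales with the
device's amplitude units and with $\sqrt{n}$, hence with the sampling
rate.  The default is meaningful for recordings on the scale the method
was developed for; reports therefore carry `n`, `n_averaged` and `fs`, and
`prv_config(normalize = TRUE)` offers interquartile-range normalization
for other hardware (off by default).

## The simulator

`generate_training_set()` reproduces the five-step construction of the
simulated index-screening cohort:

1. 50 clean single-period templates — here synthetic, built by
   `synth_template()` as a three-Gaussian mixture on normalized cycle time
   (systolic wave, dicrotic wave, diastolic decay);
2. per template, 20 base cycle durations $T_b \sim U(0.6, 1)$ s;
3. whole-template resampling to $T_b$ (1000 base waveforms), randomly
   split 500/500 into an arrhythmia and a control group;
4. per sample, 60 cycle durations $T = T_b + \Delta T$, with
   $\Delta T \sim U(-0.09, 0.09)$ s in the arrhythmia group and
   $U(-0.07, 0.07)$ s in the control group (so the 60-cycle duration range
   stays below 0.18 s and 0.14 s respectively, matching the classic
   0.16 s irregularity criterion the two groups straddle);
5. per cycle, diastole-only linear-time stretching of the sample's base
   waveform — samples before the systole/diastole boundary are copied bit
   for bit — and end-to-end concatenation.

The systole/diastole boundary is the dicrotic notch, detected as the first
local minimum after the systolic peak, with a fixed fallback at 0.35 of
the period for notchless (merged-wave) templates.  No rejection sampling
is applied to the duration ranges: the stated bounds are consequences of
the uniform laws.  Everything is a deterministic function of the seed.

**Template morphology.**  The default template peaks at 28% of the cycle,
giving a foot-to-peak crest time of roughly 0.17–0.28 s across
$T_b \in (0.6, 1)$ s — the rounded, late-peaking radial waveform typical
of elderly inpatients measured with a cuff-type pressure sensor.  Crest
time is not a free detail here: the limb distance discriminates the two
jitter laws only while the second-limb smear (spread $2w$ up to 0.18 s)
does not fully saturate the upstroke, which requires a crest time of
comparable magnitude.  A fast wearable-PPG-like upstroke (crest
$\sim$0.1 s) sits deep in saturation and no template diversity setting
recovers the published discriminability there.

**Template heterogeneity.**  Inter-individual variation is modelled as a
log-normal amplitude scale plus small jitters of the mixture parameters.
The limb distance is very sensitive to waveform timing (a few percent of
shape jitter changes $D_e$ by tens of percent, because the limb anchors
slide along flat minima), so the jitter magnitudes cannot be taken from
morphological surveys; they are instead calibrated so that the synthetic
screening cohort reproduces the discriminability reported for real
templates, the only empirical anchor available for this quantity.  The
calibrated values (amplitude scale sd 0.02; component amplitude and width
sd 0.02; centre sd 0.002 of the cycle) are deliberately small, consistent
with a device that outputs calibrated units — a single clinical decision
threshold across patients presupposes comparable amplitude scales.

**What the simulator does not emulate.**  Additive sensor noise, motion
artefacts, baseline wander and respiratory coupling (available as options
in `simulate_rhythm()` but off in the training set); real morphology
diversity; non-stationary rhythms; and realistic ectopy density — the
`PC` fixture uses a strict normal–normal–early(−25%)–pause(+25%) pattern,
which makes half of all adjacent-period intervals off-time.  Consequently
the synthetic PC cohort has a *large* limb distance (a worst case for
PC/AF separation) while still showing the qualitative PC signature: a
bulge in the first-period diastole of the averaged waveform where the
early beats' upstrokes accumulate.  Passing tests on this cohort
demonstrate the mechanics of the method under its stated assumptions, not
clinical performance on real recordings.

## Numerical and design choices

* Forward difference, left-aligned, as the derivative; the simplest
  differentiator keeps hand oracles exact.
* Round half away from zero for expansion margins; 0-based half-open
  window arithmetic internally, 1-based indices at the R surface.
* Earliest index on tied extrema everywhere, making every stage
  deterministic; `select_threshold` is a pure function of its input.
* Zeros count toward the averaging mean (denominator $N$); a
  coverage-based denominator was considered and rejected because the
  published decision threshold was obtained under the literal mean, and
  the coverage counts are retained instead so limb extraction can trim.
* AUC by the rank (Mann–Whitney) formulation, ties counted one half;
  operating points use the same strictly-greater convention as the AF
  decision.  Pairwise group comparisons follow the Dunn convention
  (mean-rank difference, tie-corrected standard error, Bonferroni), which
  matches the statistic/standard-error layout of standard post-hoc output.
* Problem sizes: the full screening experiment (1000 samples of 60 cycles
  at 500 Hz) is exercised in the acceptance test and script; unit and
  property tests run the same code paths at 100–250 Hz with 20–40 cycles,
  which the mechanics are invariant to.

## Known limitations

* The default quality screen is a heuristic stand-in for a trained
  classifier; on heavily corrupted real data the pluggable interface
  should be given a proper model.
* The decision threshold is device-scale-bound, as discussed above.
* The limb anchors (global minima over half-frames) are the method's
  soft spot: on waveforms with long flat minima they can slide by many
  samples for tiny shape changes, which both inflates the variance of the
  indexes across morphologies and creates the degenerate-frame failure
  mode at extreme jitter-to-cycle ratios.  The Manhattan and cosine
  indexes are affected more strongly than the Euclidean one, because the
  anchor-induced differences concentrate in the low-amplitude portion of
  the limbs, where $D_m$ weights them fully, and with near-stereotyped
  templates the cosine index retains some genuine rhythm signal rather
  than sitting at chance.
* Premature-contraction detection from the diastolic bulge is out of
  scope; the bulge is only asserted qualitatively.
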