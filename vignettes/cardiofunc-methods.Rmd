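---
title: "Quantitative phenotyping of iPSC-derived cardiomyocytes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phenotyping of iPSC-derived cardiomyocytes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofunc)
```

cardiofunc quantifies three functional readouts of cultured cardiomyocytes
— sarcomere organization from immunofluorescence images, calcium-handling
kinetics from fluorescence traces, and contractility from beating-monolayer
videos — and runs the group statistics used to compare genotypes and
treatments. A seed-controlled synthetic-data generator produces all three
raw-data types with known ground truth, so every stage of the pipeline is
validated by parameter recovery rather than by eye.

## Sarcomere organization: power and period

Z-discs labelled by alpha-actinin form a quasi-periodic striation pattern
with a spacing (sarcomere length) of roughly 1.6-2.2 um. The score works in
the frequency domain:

1. the image (or a rectangular ROI, at least 32 x 32 px) is mean-subtracted
   and tapered with a separable periodic Hann window to suppress
   edge-discontinuity leakage;
2. the squared-magnitude 2D DFT is computed with frequency axes in
   cycles/um;
3. the primary peak is sought in the annulus of frequencies corresponding
   to periods inside a configurable band (default 1.2-3.0 um, bracketing
   physiological sarcomere lengths while excluding DC and high-frequency
   noise). Searching an annulus over all orientations, rather than a 1D
   line profile, makes the score rotation invariant and removes the need
   to know the myofibril direction;
4. **period** is 1/peak-frequency. The search runs on a 4x zero-padded
   (sinc-interpolated) spectrum so closely spaced maxima are resolved, is
   refined by 3-point parabolic interpolation of the log-power along the
   ray through the peak, and is then polished to the continuum maximum of
   the windowed spectrum along that ray (golden-section on a direct DFT
   evaluation). In tests this estimate agrees with an exhaustive dense
   direct-DFT argmax to within half of a 10x-refined frequency bin;
5. **power** is the energy in the 3 x 3 original-grid bin neighborhood of
   the peak (plus its Hermitian mirror), divided by the total off-DC
   energy. The neighborhood captures the window-spread leakage of the
   fundamental without absorbing harmonics. The ratio lies in [0, 1], is
   invariant to intensity scaling, and decreases monotonically as the
   positional disorder of the bands grows — the ordering semantics of
   "higher power = more organized".

The scale of this power score is a declared design choice: a normalized
energy fraction rather than an absolute spectral magnitude, because an
absolute value would depend on staining intensity and exposure. Constant
(blank) images are flagged `no_signal` and score zero rather than erroring,
so batch runs survive empty fields.

ROIs are scored independently; averaging multiple ROIs of one cell happens
at the statistics layer, never inside the score. Coordinates are 0-based,
half-open, row-major with the origin at the top-left.

## Calcium transients

Each beat is modelled as a linear rise to the peak over the rise time,
followed by a mono-exponential decay with time constant tau that relaxes to
the diastolic level. Two acquisition modes are supported, mirroring common
practice: spontaneous single-channel (Fluo-4-like) recordings, and paced
ratiometric (Fura-2) recordings in which the F340/F380 excitation ratio is
the calcium-proportional signal.

**Detection.** Peaks are local maxima with prominence at least 5 robust
noise SDs, where the noise SD is the scaled median absolute deviation of
the first differences — a measure untouched by the transients themselves.
Peaks closer than a refractory window (a quarter of the expected period)
merge, keeping the higher; in paced mode at most one peak is accepted per
pacing cycle. The onset of a beat is the last crossing of
diastolic + 10 % amplitude before its peak. The 10 % convention makes the
measured rise time 0.9x of the generator's linear ramp, within one sample.

**Features.**

* *diastolic level*: median over inter-beat baselines (last 25 % of each
  onset-to-onset interval);
* *amplitude*: mean of (peak - preceding diastolic);
* *rise time*: mean onset-to-peak time;
* *decay tau*: per-beat least-squares fit of `A exp(-t/tau) + C` from one
  sample after the peak to one sample before the next onset (the sampled
  maximum can sit on the rising ramp; any suffix of the decay is still
  mono-exponential, so starting one sample later is exact). The offset `C`
  absorbs the diastolic level. Fits with r-squared below 0.8 are excluded
  from the cell mean as merged-beat guards. For the final beat, the window
  stops at the trace minimum so a truncated next beat cannot contaminate
  the fit;
* *beat rate*: `60 (n-1) / (t_last_peak - t_first_peak)` — span-based, so
  partial first/last cycles cause no bias.

Single-channel traces are normalized to F/F0 with F0 the 10th percentile of
the trace, which makes all kinetic features invariant to detector gain. One
known consequence, stated here because it shapes the pipeline: with
additive noise the 10th percentile sits about one noise SD below the true
baseline, so the *absolute* diastolic level of a dF/F0 trace is biased and
group differences in baseline calcium are not measurable in this mode. That
is the physical reason the ratiometric protocol exists, and the pipeline
accordingly measures diastolic level (and amplitude, in ratio units) from
the paced ratiometric traces. Ratio traces are never re-normalized: the
ratio is already concentration-calibrated up to a constant.

Parameter recovery under the reference conditions (paced 0.5 Hz ratiometric
traces, 20 s at 50 samples/s, tau 0.4 s, amplitude-to-noise ratio 20 dB, 50
cells) gives median relative errors of about 3 % for tau and about 2 % for
amplitude and diastolic level; spontaneous single-channel tau recovers to
the same accuracy. These numbers are recomputed by the test suite and by
`scripts/acceptance.R` on every run.

## Monolayer motion

Contractility is read from the frame-to-frame displacement of a beating
monolayer, as commercial cell-motion imagers do. For each adjacent frame
pair the first frame is tiled into blocks (default 16 px) with a margin
equal to the search radius (default 7 px); each block with intensity
variance above a texture floor is matched against the second frame by
exhaustive normalized cross-correlation over integer offsets, refined to
sub-pixel precision by separable 3-point parabolic interpolation of the
correlation surface. Perfect matches stay integer, which keeps pure
translations exact; ties break toward the smaller displacement. NCC was
chosen over gradient-based optical flow because it is exact for
translations and immune to global intensity drift. The exhaustive search is
compiled (C++); everything else is R.

The mean displacement magnitude over valid blocks, scaled by pixel size
over frame interval, gives the per-pair speed in um/s. Beats are segmented
where the speed exceeds 10 % of its global maximum; the speed passes
through zero between the contraction and relaxation phases of a single
beat, so quiescent gaps much shorter than the longest (inter-beat) gap are
bridged before segmentation. Within each beat episode the first prominent
peak is the contraction peak and the last the relaxation peak; peak values
are refined by a 3-point parabola to recover the maximum lost to
frame-interval sampling, and durations are widths at half prominence. The
beating-area fraction is the fraction of valid blocks whose per-beat
maximum displacement exceeds a threshold (default 0.2 px, configurable and
reported with results — the quantity has no standard definition, so the
operational one is explicit). Across generator peak velocities of 2-20 um/s
the recovered contraction peaks regress on truth with a slope within
[0.9, 1.1].

## Group statistics

Measurements arrive as a long table of per-cell values under two crossed
factors (genotype x treatment). `two_way_anova()` uses the classical
sum-of-squares partition when the design is balanced and Type-II sums of
squares (via `car::Anova()`) otherwise — cell counts in real imaging
experiments are rarely equal, and Type II is the conventional default when
no interaction-priority is stated. Zero-variance degenerate tables report
an undefined F with p = 1 and a flag instead of erroring, keeping batch
runs alive. Post hoc comparisons are all pairwise cell-mean contrasts using
the pooled error mean square (Welch-unpooled optional), with step-down
Sidak (Holm-Sidak) adjustment:
sort the m raw p-values ascending, adjust the i-th to
`1 - (1 - p_(i))^(m - i + 1)`, enforce monotonicity by running maximum, and
report in input order. The family of comparisons is explicit in the output
— which contrasts entered the adjustment is a reporting decision, not a
hidden one. Under a simulated null (four groups of Normal(0,1), n = 30,
1000 replicate tables) the factor-A F-test rejects at a rate inside the
exact binomial 99 % interval around 0.05.

Relative gene expression from qPCR follows the 2^-ddCt scheme: technical
replicates are averaged per sample and gene, dCt is the target-minus-
reference Ct, ddCt subtracts the calibrator group's mean dCt, and the fold
change is 2^-ddCt. Because the anchoring happens on the Ct (log) scale, the
calibrator group's *geometric* mean fold is exactly 1; the arithmetic mean
exceeds 1 whenever the group has spread, which is a property of the method
itself and not an implementation artifact.

## The synthetic-data generator

The generator inverts each measurement, with every random draw under an
explicit seed (identical seeds give bit-identical outputs):

* **Striation images** — Gaussian-profile ridges (matching the
  diffraction-blurred appearance of Z-disc staining, and giving a clean
  spectral fundamental) spaced by the period along a configurable
  orientation, with independent Normal positional jitter per band and
  additive Gaussian pixel noise. Jitter is the disorder dial: mean power
  falls strictly as jitter grows from 0 to 0.5 um.
* **Calcium traces** — sums of linear-rise/exponential-decay kernels on a
  diastolic baseline. Paced rhythm places onsets at exact multiples of the
  pacing period; spontaneous rhythm jitters inter-beat intervals with a
  5 % CV (rhythm variability of spontaneously beating cultures is not a
  reported quantity; a small CV keeps beats separable, which is the regime
  the analysis assumes). Ratiometric mode synthesizes a constant-mean F380
  channel and sets F340 = R(t) x F380, so the ratio reconstructs R(t)
  exactly; any factorization with the correct ratio is observationally
  equivalent for the pipeline. Two invariants are enforced at construction:
  transients resolve between beats (rise + 3 tau < period) and sampling is
  at least 20x the beat rate.
* **Beating videos** — a static band-pass noise texture (correlation
  length ~4 px, so block matching has texture everywhere) warped by
  `d(x, t) = m(x) s(t) u`, with `m` a smooth mask occupying the beating
  area fraction, `u` a fixed direction and `s(t)` a per-beat raised-cosine
  displacement pulse whose derivative attains +peak contraction velocity on
  the rise and -peak relaxation velocity on the fall. The active phase
  occupies half the beat period, split between rise and fall in inverse
  proportion to the two peak velocities. The attached ground-truth signed
  velocity series integrates to zero over each beat.
* **Group datasets** — per-cell parameters drawn from truncated-Normal
  distributions (truncation at physical bounds prevents negative taus and
  amplitudes at large SDs) per factor combination, then materialized
  through the generators above. The truth table never reaches the analysis
  code. The bundled `pln_stress_design()` encodes a
  corrected-vs-mutant x baseline-vs-metabolic-stress experiment in which
  the stressed mutant has amplitude -30 %, diastolic +20 %, tau +30 %,
  peak velocities -30 % and tripled striation jitter; at 50 cells/group and
  20 dB SNR the pipeline flags all five effects with the correct signs at
  Holm-Sidak adjusted p < 0.05.

What the generator does *not* emulate — and what passing tests therefore do
not certify for real data: optical point-spread functions, photobleaching
and focus drift, arrhythmic or alternans beating, cell segmentation, and
myofibrils with spatially varying orientation within one ROI. The
generator's role is to verify the estimators under the model they assume;
robustness to model violations must be judged separately.

## Problem sizes and numerical choices

Validation runs use sizes chosen to exercise every code path at
interactive speed: striation images of 64 x 256 px at 0.1 um/px (≥ 10
periods along the band normal, the generator's hard requirement), traces of
20 s at 50 samples/s (~8-10 beats), videos of 50 frames of 64 x 64 px at 20
fps covering ≥ 2 beats, and 50 cells per group for power-style checks.
Decay fits use `minpack.lm::nlsLM` with analytic-ish starting values (offset
from the segment minimum, tau from the 1/e crossing); spectra use the FFT
with a periodic Hann window; ties in the spectral argmax break toward lower
frequency then smaller angle, and in block matching toward smaller
displacement then lexicographic order, so results are exactly reproducible
across platforms.

## Known limitations

* The power score depends on the window placement for patterns whose
  period does not divide the image size; translation invariance holds to
  <1 % for in-register patterns and degrades gracefully otherwise.
* Absolute diastolic level is only meaningful in ratiometric mode (see
  above).
* Beating-area fraction compares the moving-block count against the block
  grid, which excludes a margin of one search radius around the frame;
  with small frames the margin inflates the estimate relative to the
  whole-frame fraction.
* The decay model is a single exponential; biphasic decays will be
  summarized by an effective tau with a reduced fit r-squared.
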