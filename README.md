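# cardiofunc

Quantitative functional phenotyping of iPSC-derived cardiomyocytes
(iPSC-CMs) in R. Disease-modelling studies of cardiomyopathy mutations —
for example phospholamban variants that derange SERCA-mediated calcium
reuptake — compare genotypes and treatments on three standard readouts,
and this package implements all three plus the downstream statistics:

* **Sarcomere organization** from alpha-actinin/TNNT2 immunofluorescence:
  the image is Hann-windowed and Fourier-transformed, and the primary peak
  of the 2D power spectrum inside a sarcomere-length band (default
  1.2–3.0 µm) yields the mean sarcomere length ("period",
  `1/f_peak`) and a regularity score ("power"), defined as the peak-
  neighborhood energy fraction of total off-DC energy — higher power,
  more organized striations.
* **Calcium-transient kinetics** from spontaneous single-channel (Fluo-4)
  traces or paced ratiometric (Fura-2, F340/F380) pairs: beat rate,
  amplitude, 10 %-to-peak rise time, mono-exponential decay constant
  (`A e^{-t/τ} + C` per beat), and diastolic level.
* **Monolayer contractility** from time-lapse videos: block-matching
  normalized cross-correlation gives per-frame displacement fields; the
  mean speed trace is segmented into beats, yielding contraction and
  relaxation peak velocities (µm/s), their durations, and the beating-area
  fraction.
* **Group statistics**: one-/two-way fixed-effects ANOVA (classical
  partition when balanced, Type-II sums of squares when not), Holm–Šidák
  step-down pairwise comparisons
  (`adj_i = 1 − (1 − p_(i))^(m−i+1)`, monotone-enforced), pooled
  Student's t-tests, mean ± SEM summaries, and 2^−ΔΔCt relative gene
  expression.

A fully seed-controlled synthetic-data generator produces striation
images, calcium traces and beating videos with recorded ground truth, so
every estimator is validated by parameter recovery. See the methods
vignette (`vignettes/cardiofunc-methods.Rmd`) for models, assumptions and
numerical choices.

## Worked example

```r
library(cardiofunc)

# a striation image with known 1.8 µm period and 0.1 µm band jitter
img <- generate_striation_image(
  striation_truth(period_um = 1.8, jitter_sigma_um = 0.1,
                  noise_sd = 100, seed = 1),
  shape = c(64, 256), pixel_size_um = 0.1)
score_sarcomere(img)
#>   power period_um orientation_deg peak_frequency_cyc_per_um no_signal
#> 1 0.744      1.79               0                     0.559 FALSE
```

The period is recovered to 1.79 µm (truth 1.8); the power of 0.74 is the
fraction of off-DC spectral energy concentrated at the striation
frequency — it falls toward 0 as the bands become disordered.

```r
# a paced (0.5 Hz) Fura-2-style ratio trace: diastolic ratio 0.5,
# transient amplitude 0.6, decay tau 0.4 s, 20 dB noise
rt <- generate_calcium_trace(transient_truth(
  mode = "ratiometric", rhythm = "paced", beat_rate_hz = 0.5,
  amplitude = 0.6, diastolic_level = 0.5, decay_tau_s = 0.4,
  noise_sd = 0.06, seed = 2))
analyze_calcium_trace(rt, rhythm = "paced", pacing_hz = 0.5)
#>   beat_rate_bpm amplitude rise_time_s decay_tau_s diastolic_level n_beats
#> 1          30.1     0.606      0.0960       0.432           0.499      10
```

All ten paced beats are found; amplitude (0.606 vs 0.6), diastolic ratio
(0.499 vs 0.5) and tau (0.432 vs 0.4) recover the programmed kinetics.

```r
# a beating monolayer video: contraction peak 10 µm/s, relaxation 5 µm/s
vid <- generate_motion_video(motion_truth(10, 5, seed = 3))
beat_kinetics(velocity_trace(vid))
#>   contraction_peak_um_s relaxation_peak_um_s contraction_duration_s ...
#> 1                  10.0                 5.04                    0.1
```

`run_pipeline()` chains everything: it simulates a 2 × 2
genotype-by-treatment study (`pln_stress_design()`), scores every cell,
and runs the two-way ANOVA with Holm–Šidák comparisons per measurement,
writing provenance-stamped CSVs. A thin command-line wrapper with
`run | simulate | sarcomere | calcium | motion | stats` subcommands is
installed at `inst/scripts/cardiofunc`.

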