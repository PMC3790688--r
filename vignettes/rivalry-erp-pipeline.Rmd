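---
title: "Predicting perceptual alternations from first-display ERPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting perceptual alternations from first-display ERPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalerp)
```

## The paradigm and the question

In intermittent binocular rivalry, a display of orthogonal gratings — one
orientation to each eye — is shown briefly, interrupted by a dark gap, and
shown again. The interruption tends to time-lock perceptual alternations to
the re-onset of the display, so each trial yields a clean binary outcome: the
visible orientation after the gap either *changed* or stayed the *same*,
with no change in the physical stimulus. The scientific question this
package's pipeline addresses is whether brain activity during the **first**
display, measured with EEG, predicts that later change in visual
consciousness. Fusion trials — identical gratings to both eyes, which can
only change perceptually if the stimulus changes physically — serve as the
negative control: no first-display signal can legitimately "predict" what a
computer will later choose to display.

Each trial is S1 (1000 ms) → gap (200 ms) → S2 (1000 ms) → mask (1000 ms) →
ITI (2000 ms), so successive S1 onsets are exactly 5200 ms apart. A session
is 16 blocks of 40 trials, half rivalry and half fusion in every block, with
orientations counterbalanced and order randomised afresh per block except
that the condition of each block's first trial alternates. The analysed
group is 11 participants, which fixes the error degrees of freedom of every
group test (paired t and within-subject F denominators of 10).

## What the synthetic-data generator emulates

Because no raw recordings are distributed, every stage is driven by a
generator whose defaults *are* the study conditions:

* **Design** (`make_design`): the block structure, counterbalance, and
  5200 ms trial spacing above.
* **Behaviour** (`simulate_behavior`): rivalry outcomes are i.i.d.
  multinomial draws with means 37% changed / 57% same / 6% no response;
  fusion responses are correct with probability 94%. The study reports
  between-participant SDs (14, 10 and 7 percentage points), so
  per-participant probabilities are drawn from Beta distributions
  moment-matched to those means and SDs
  (`behavior_hyperprior`, `draw_participant_behavior`). This reproduces both
  the group means and the between-participant spread.
* **EEG** (`simulate_recording`): each display onset evokes three
  stereotyped components — a posterior P1 (100 ms), a posterior N1
  (180 ms), and a broad central late positivity rising at 300 ms, peaking
  at 400 ms and decaying by 800 ms. Waveforms are Gaussian-windowed
  half-period cosines (the late positivity an asymmetric raised-cosine
  ramp); scalp patterns are Gaussian falloffs in geodesic distance from a
  component-specific centre (POz for P1/N1, Cz for the late positivity), or
  forward-projected dipoles when a gain matrix is supplied. The two
  predictive effects are injected only on rivalry trials whose percept later
  changes: the S1 N1 is deepened by `n1_extra_negativity_uV` and the S1
  late positivity reduced by `lp_reduction_uV`. Fusion S1 responses never
  depend on the outcome. Background noise is 1/f-shaped plus white sensor
  noise; blinks (`inject_blinks`) are large frontal transients at Poisson
  times whose ground-truth times are retained for rejection testing.

Free parameters the study does not print, fixed once as realistic values:
base component amplitudes (+5, −8, +6 µV — conventional visual-ERP
magnitudes), effect sizes (2 and 1.5 µV — the order of the plotted
condition differences), background RMS 8 µV (post-filter peak-to-peak
background then sits mostly under the 60 µV EOG bound, so rejection is
driven by blinks, and rejection rates land near the study's ~20%), and a
blink rate of 0.1/s. None of these is a reported quantity; they are the
generator's own study-plausible choices and the documentation of record is
this section.

What the generator deliberately does **not** emulate: rivalry dynamics
(dominance-duration distributions, onset rivalry), trial-to-trial latency
jitter of components, spatially correlated background (channels are
independent before referencing), alpha rhythms, and non-blink artifacts.
Passing tests therefore show that the *pipeline* is correct and calibrated,
not that real EEG satisfies these simplifications.

## Preprocessing

The preprocessing chain follows the study's stated parameters exactly:

1. **Re-referencing** (`rereference`): offline to the mean of the two
   earlobe electrodes ("linked earlobes"); the recording reference FCz
   thereby becomes an ordinary scalp channel, giving 59 informative scalp
   channels.
2. **Filtering** (`design_fir`, `filter_apply`): 0.3–35 Hz Kaiser windowed
   sinc FIR, 1857 points, Kaiser β = 5.65326 (exactly the Kaiser-formula β
   for 60 dB design attenuation). The kernel is the difference of two
   windowed-sinc lowpass kernels, each normalised to unit DC gain after
   windowing — without that normalisation the truncation-dominated 0.3 Hz
   kernel would leave tens of dB of DC leakage. Filtering is single-pass
   linear phase with the integer group delay (928 samples) compensated, so
   event latencies are preserved exactly and the amplitude response equals
   the design response; the 928 edge samples at each end are flagged
   unusable. The simulator's 2 s lead-in pad keeps them out of every epoch.
3. **Epoching** (`extract_epochs`): a 2100 ms window time-locked to S1
   onset, −100 to 2000 ms, both endpoints inclusive on the sample grid —
   1051 samples at 500 Hz. Whether the study's own window endpoint was
   inclusive is not stated; this convention is declared, not inferred.
4. **Baseline** (`baseline_correct`): subtract the −100–0 ms mean per epoch
   and channel; idempotent.
5. **Artifact rejection** (`reject_artifacts`): peak-to-peak exceeding
   60 µV on any EOG channel or 150 µV on any scalp channel rejects the
   epoch. Fusion epochs with incorrect responses and rivalry no-response
   epochs are excluded at the averaging stage, which also excludes any
   participant left with an empty condition cell (mirroring the study's
   participant-exclusion rule).

## The statistical battery

**Pointwise t-maps** (`pointwise_tmap`): at every (electrode, sample) cell,
a two-sided paired t across participants on the changed-minus-same
participant-level ERP difference, df = n − 1 = 10, displayed thresholded at
p = .01 uncorrected. The multiple-testing stance mirrors the study: maps are
uncorrected, with three guards rather than a cluster correction.

**ROI counting and the chi-square guard** (`roi_spec`, `roi_count`,
`count_chisq`): the pre-declared ROI is the ten parieto-occipital/occipital
electrodes over 80–250 ms. Samples use the half-open convention
[start, end) at the 2 ms grid — the only convention that yields the printed
85 samples, hence 10 × 85 = 850 cells and a null expectation of 8.5
significant tests at α = .01. The observed count is referred to a
one-degree-of-freedom goodness-of-fit chi-square over the two cells
significant/not significant; for the study's 34 observed tests this gives
χ²(1) = 77.27. The same half-open rule gives the 170–190 ms window 10
samples and the 380–420 ms window 20.

**Permutation guard** (`permutation_tmap`): "running permutation tests" are
operationalised as cellwise sign-flip permutation of the paired
differences. At n ≤ 12 all 2ⁿ sign assignments are enumerated — 2048 for 11
participants — making the test exact and seed-free; the identity assignment
is part of the enumeration, so p ≥ 1/2048, and the attainable level just
below α = .01 is 20/2048 ≈ 0.977%, a discreteness worth remembering when
reading calibration numbers. The observed statistic is thresholded against
the enumeration's own identity row, which keeps the count correct even
where near-zero variance makes t numerically delicate.

**Windowed rm-ANOVA** (`window_mean`, `rm_anova`): voltages averaged over a
six-electrode cluster and a window (posterior cluster at 170–190 ms for the
N1 effect; central cluster at 380–420 ms for the late-positivity effect)
enter a within-subject ANOVA by sums-of-squares decomposition, each effect
tested against its own subject-by-effect interaction, with partial
η² = SS_effect/(SS_effect + SS_error). For a two-level single factor F is
exactly the squared paired t, and with 11 participants the dfs are the
printed F(1, 10). One- and two-factor designs are supported; the exact
second factor of the study's supplementary two-factor tables is not
recoverable from the text, so the factor mapping is left to the caller.
Cluster membership and the ROI electrode identities are configuration, not
fact — the study shows them only as schematic heads; the defaults here are
the natural choices in the default montage.

## Source analysis (simplified)

The study's distributed inverse is emulated at reduced fidelity, keeping
the statistical pipeline intact while removing the anatomical machinery:

* **Forward model** (`make_leadfield`): quasi-static dipole in a
  homogeneous unit sphere, computed by the truncated Legendre series of the
  surface potential (120 terms; the series converges geometrically in
  source eccentricity). The gain matrix is referenced the same way as the
  data (linked earlobes by default) and is shared verbatim between forward
  simulation and inversion.
* **Inverse** (`inverse_operator`): Tikhonov-regularised least squares with
  a discrete-Laplacian smoothness penalty on the voxel grid — the
  "spatially smoothest current density" idea without the grey-matter
  restriction. λ defaults to generalized cross-validation on the supplied
  (typically group-average) data, since no regularisation constant is
  reported.
* **Group maps** (`spm_hotelling`, `spm_condition_contrast`): voxelwise
  one-sample Hotelling T² of the 3-component current vectors against zero,
  F-transformed with df (3, n − 3) — (3, 8) at n = 11 — and the paired
  contrast between conditions on the per-participant differences.
  Bonferroni correction replaces random-field theory; the study itself
  reports Bonferroni-corrected maps, so the reported correction is kept and
  only the spatial-dependency refinement is dropped.
* **Grid**: the full-scale description (3,244 voxels of 7 mm) is a
  configuration; tests and examples run a ~300-voxel grid (spacing 0.2 of
  the head radius) so the whole SPM computes in seconds.

Known limitations: a homogeneous sphere ignores skull conductivity, so
absolute current magnitudes are arbitrary units; minimum-norm-type inverses
bias deep sources toward the surface (recovery tests therefore use
superficial sources, where localisation is within one voxel spacing); and
Bonferroni over correlated voxels is conservative.

## Numerical choices and degenerate inputs

* Zero-variance t-map cells are undefined; they are flagged not significant
  with a warning rather than silently zeroed.
* Voxels with singular 3 × 3 covariance are untestable (`NA`, never
  significant); all-zero solutions produce an all-`NA`, nothing-significant
  map.
* Epochs overlapping record boundaries are dropped with a count; an event
  at the very start of a record has no baseline and is dropped.
* Rejection thresholds are monotone by construction: raising either bound
  never rejects more.
* The epoch/window sample conventions (inclusive epochs, half-open analysis
  windows) are fixed package-wide; every window documents its sample count.
* Seeding: one master seed spawns independent child seeds per participant
  and per replicate (`spawn_seeds`), so runs are reproducible bit for bit
  and participants are independent streams.

## Calibration and recovery studies

`calibrate_type1()` measures the Type-I rate of both map types on replicate
null studies (all condition effects zero) and of the fusion contrast on
effect-bearing studies, using the ERP-level generator
(`simulate_erp_study`) — the participant-level averages the full pipeline
converges to, with temporally **white** residual noise. White noise is the
deliberate choice here because it makes the cell-level significance count
exactly binomial, so the nominal 99% band around 1% is an honest yardstick;
with temporally correlated noise the count would be over-dispersed for any
per-cell band, which is a property of dependence, not miscalibration. The
full continuous pipeline is separately property-tested on end-to-end
datasets with a loose per-dataset bound for exactly that reason. At the
default sizes (200 datasets × 850 cells) the calibration run takes well
under a minute.

`power_n1()` replicates the 170–190 ms posterior-cluster ANOVA with a known
injected N1 effect (default three times the residual ERP noise SD) and
checks both detection rate and unbiasedness of the recovered
changed-minus-same window difference against the generator's analytic
expectation (`injected_window_difference`, which accounts for the
linked-earlobe reference of the analysed data). With 11 participants and a
20% between-participant amplitude spread, power at the 3σ effect is
essentially 1.

## Design decisions that were genuinely open

* **Component waveforms**: no closed form is given for the study's ERPs;
  Gaussian-windowed half-period cosines are standard ERP-simulation
  practice and fully parameterised.
* **Topographies**: Gaussian geodesic falloff decouples ERP tests from
  forward-model fidelity; the gain-matrix route exists for source tests.
* **Permutation scheme**: no scheme is described; full sign-flip
  enumeration is exact at this n and removes the seed from the guard.
* **Earlobe reference**: the arithmetic mean of the two earlobe channels,
  the standard meaning of "linked earlobes".
* **Pipeline scale in tests**: examples and tests run reduced sizes (fewer
  trials, ~20-channel montages, ~300-voxel grids) chosen so the full suite
  and the reproduction script complete in minutes while every df-bearing
  quantity (11 participants, 850 ROI cells, 2048 sign assignments) stays at
  study scale.
* **Epoch persistence**: pipeline runs persist epochs as RDS; the
  BrainVision triplet is the interchange format for continuous data, and
  trial tables, stat maps and SPMs are TSV.

## What the pipeline does not do

No ICA or regression-based ocular correction (the study rejects epochs, it
does not correct them); no cluster-based permutation statistics; no
time-frequency analysis; no anatomical labelling of sources; no stimulus
rendering or psychophysical rivalry model.
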