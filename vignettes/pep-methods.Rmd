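---
title: "Perturbation-evoked potentials: model, pipeline and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-evoked potentials: model, pipeline and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Sudden support-surface translations evoke a cortical response -- the
perturbation-evoked potential (PEP) -- within roughly 90-150 ms of
perturbation onset. Its magnitude grows when the perturbation is
unpredictable, plausibly because a startle response superimposes on the
postural reaction, and ear-EEG electrodes over the mastoid bone may capture
this response well enough to serve as a single-sensor marker of a balance
threat. `pepkit` implements the full analysis chain for such experiments --
from synchronized multi-rate raw recordings to split-plot ANOVA -- together
with a synthetic-cohort generator that emulates the study design, so every
stage can be exercised and tested without access to any recordings.

## The trial protocol

The stock protocol (`build_default_protocol()`) delivers 34 platform
translations: posterior throughout, except anterior "catch" translations at
trials 16, 22, 28, 29 and 34. Trial 1 (the first, unannounced perturbation)
and the five anterior trials are analyzed as *unpredictable* (6 events);
trials 2-5 are *excluded* as habituation trials; the remaining 24 posterior
trials are *predictable*. Protocols are data, not code: any alternative
sequence satisfying the type's invariants can be supplied as a table.

## Platform kinematics

Translations are 20 cm at a 0.2 g acceleration ceiling with a requested
peak velocity of 1 m/s. These three numbers are not jointly realizable by
an accelerate-cruise-decelerate profile: reaching 1 m/s at 0.2 g alone
covers ~25.5 cm. The package honours acceleration and displacement exactly
and caps peak velocity at `sqrt(a d)` (~0.63 m/s), giving a triangular
velocity profile; `platform_profile()` warns when the cap binds. Nothing
downstream uses peak velocity -- onset detection reads the acceleration
burst and epochs lock to onset. The two phases of the sampled trace are
rescaled by a sub-percent factor so that cumulative-trapezoid double
integration of the emitted 150 Hz samples ends at exactly the nominal
displacement with exactly zero terminal velocity; the discretized trace is
the object every consumer sees, so the discretization correction belongs in
the generator rather than in every downstream tolerance.

## Signal preprocessing

EEG (1,000 Hz; Fz, Cz and three mastoid channels per ear) is filtered
offline with a 2nd-order Butterworth band-pass (2.5-30 Hz) and a 60 Hz
notch. Because the analysis is offline and epoch latencies must not be
skewed by group delay, both filters are applied zero-phase. Two routes are
provided and tested against each other: `method = "filtfilt"` runs the
forward-backward recursion, and the default `method = "fft"` multiplies the
spectrum by the squared magnitude response of the cascade -- the
frequency-domain expression of forward-backward filtering with circular
boundary treatment. On these long continuous records with quiet ends the
two differ only near the record edges, where no epochs are taken. The notch
is an RBJ-style biquad with Q = 30; the band-pass design comes from
`signal::butter()`. Filtering precedes epoching so that no filter transient
falls inside a 300 ms epoch, and the mastoid series is averaged before
filtering (averaging and filtering commute by linearity; the identity is
covered by tests).

Perturbation onset is read from the platform accelerometer (150 Hz),
operationalizing "the first noticeable burst of activity" as the first run
of at least 3 consecutive samples deviating from the pre-marker baseline
mean by more than 5 baseline SDs, inside a 1 s post-marker search window.
All three numbers are exposed in `onset_detection_spec()` since no
published values exist; a degenerate (zero-variance) baseline falls back to
an absolute threshold of 5% of the window's peak acceleration. Undetected
events are flagged, never silently dropped. Onset times map to the EEG
clock by nearest-sample rounding.

## Epochs, correction, normalization

Each analyzable trial contributes the 300 ms of EEG following onset (300
samples), with baseline statistics from the window 300 to 100 ms before
onset; windows are half-open on the right and the onset sample belongs to
the epoch. Correction removes the least-squares linear trend from the epoch
and then expresses samples relative to the baseline: subtract the baseline
mean and divide by the baseline SD, so corrected epochs are in baseline-SD
units. The stated purpose of the step is removing linear trends and DC
shifts; a mean-only variant is available as `correction = "mean"`. Note the
detrend absorbs any constant offset in the epoch itself, and the continuous
band-pass has already annihilated DC, so corrected epochs are invariant to
a DC shift injected into the raw recording (a property the tests verify
end-to-end). Degenerate baselines (SD below 1e-12) invalidate the epoch.
Epoch state advances `raw -> corrected -> normalized` and each transition
is guarded -- reprocessing a processed epoch is an error, not a no-op.

Within each subject and channel, all corrected epochs are divided by the
maximum absolute sample of that subject's first valid event epoch (trial 1;
if it is missing the earliest valid epoch substitutes and the substitution
is recorded). After normalization the first epoch's maximum magnitude is
exactly 1 and all magnitudes are comparable across subjects. Normalization
uses corrected (baseline-SD unit) epochs -- the only form that exists at
that stage of the chain.

## Summaries and statistics

Per epoch the package computes the RMS (`sqrt(mean(x^2))`) and the peak
magnitude (the maximum signed sample -- the most prominent positive
deflection, without component scoring); per subject, channel and condition
it averages them over valid epochs. The condition table feeds a split-plot
(repeated-measures mixed) three-way ANOVA per channel: age group and sex
between subjects, perturbation type within. With a two-level within factor
the model reduces exactly to two between-subject analyses -- subject
condition means for the between stratum, condition differences for the
within stratum -- fitted with sum-to-zero coding so each 1-df F is the
partial (Type III) test and unbalanced groups are handled; every effect is
tested on (1, N-4) degrees of freedom with N the listwise-complete subject
count. The implementation is verified against `stats::aov` with an error
stratum and against a hand-computed sums-of-squares decomposition.
Post-hoc, the four age x sex cells are compared with Tukey's HSD
(studentized-range distribution, Tukey-Kramer harmonic-mean cell sizes)
against the between-subject error stratum at alpha = 0.05. Effect sizes are
Cohen's d with pooled-SD standardization; for the within-subject condition
effect the classical between-condition pooled SD is used, not the
difference-score dz, and the definition is recorded in the output. Sign
conventions: unpredictable - predictable, elder - young, male - female. No
correction across channels is applied, mirroring per-channel reporting
practice.

## The synthetic cohort generator

`generator_config()` encodes the study conditions: 40 subjects (10 per
age-group x sex cell), 34 trials at fixed 7 s intervals, EEG at 1,000 Hz,
platform acceleration at 150 Hz synchronized by shared event markers, a
uniform 0-30 ms marker-to-motion delay, and 40 events across the cohort
flagged incomplete at random (yielding the 1,200 planned / 1,160 analyzed
accounting).

**Background.** Channel noise is band-limited (1-45 Hz) 1/f Gaussian noise
synthesized in the frequency domain, scaled to a 10 uV SD, plus a 5 uV
line component at 60 Hz so the notch is exercised. A per-subject lognormal
recording scale (log-SD 0.3) multiplies signal and background alike --
exactly the cross-subject amplitude differences that baseline z-correction
and first-trial normalization exist to remove.

**Evoked response.** Each trial adds a biphasic atom: a sharp negative
lobe (fast attack, 1.4x the positive peak -- the steep early negativity of
perturbation responses) followed by a broader positive lobe, 120 ms long,
at a latency drawn uniformly from 90-140 ms after motion onset. Base
positive-peak amplitudes (Fz 18, Cz 18, mastoid 22 uV) are set so a
predictable trial's single-channel evoked-to-background RMS ratio is about
one -- low enough that baseline correction, normalization and trial
averaging matter. Per-trial lognormal jitter (log-SD 0.15) models
response variability.

**Effect structure.** Unpredictable trials are scaled by a per-channel
condition gain; elders by an age gain at Cz and the mastoids; elder males
by an extra mastoid gain. Trial 1 carries a `first_trial_boost` (1.8)
that is *not* modulated by the age/sex gains: the first-ever perturbation
elicits a pronounced startle that saturates across groups. This matters
structurally -- trial 1 is the normalization reference, so any gain
applied uniformly to all of a subject's trials cancels exactly in
normalized summaries; group effects are recoverable downstream only
because the reference saturates while later trials differ by group.
Condition gains (Fz 1.08, Cz 1.045, mastoid 1.156) were calibrated once by
simulation -- regressing recovered d on gain over seeded cohorts -- so the
full pipeline recovers a perturbation-type Cohen's d of ~0.5 at the
mastoid, ~0.3 at Fz and ~0.2 at Cz; the calibrated configuration ships in
`inst/extdata/default_config.yaml`.

**Determinism and the fused fast path.** The master seed fixes the subject
table, per-subject seeds and dropout assignment, so cohorts can be built
all at once or streamed one subject at a time with identical results. For
Monte-Carlo work `run_cohort_analysis(fast = TRUE)` (the default) fuses
synthesis and filtering: because both are linear and time-invariant, the
zero-phase gain is applied to the sparse noise spectra before the inverse
FFT and a pre-filtered copy of the atom is added in the time domain. The
fused route draws random numbers in exactly the reference order and is
tested to agree with simulate-then-`process_recording()` to ~1e-8 in the
corrected epochs.

**What the generator does not emulate.** No body-sway biomechanics, EMG or
ocular artifacts, no habituation across the excluded trials 2-5, no
group-specific latency shifts (a configuration hook, not a default), and
dropout is missing-at-random whole events. Passing tests on this synthetic
cohort therefore show that the pipeline recovers the effect structure it
was pointed at under realistic noise -- not that it is robust to artifact
classes the generator never produces.

## Numerical choices and degenerate inputs

Sub-percent phase rescaling pins sampled-trace kinematics (above);
zero-phase gains are cached per record length; the baseline-SD tolerance is
1e-12; a zero normalization reference aborts (it cannot occur with nonzero
noise); nearest-sample rounding maps onset times across clocks; ANOVA cells
with fewer than two subjects abort as an invalid design; a zero Tukey MSE
aborts as degenerate. Monte-Carlo problem sizes used by the test suite:
100 seeded cohorts for the effect-size recovery check, 20 full-pipeline
null cohorts (all gains 1) for the type-I-error band, 500 replicates for
the ANOVA-level null calibration, and 3 gain levels x 4 cohorts for the
monotonicity check -- sizes chosen so the binomial or Monte-Carlo bands
are informative at desk scale.

## Known limitations

Reported F, p and most d values from real cohorts are not reproducible
here -- no raw data accompany the design, so only the effect *structure*
is recovered on synthetic data. Published per-effect d values of 5.1 or
1.6 alongside F(1,34) of 6.6 and 4.6 are mutually inconsistent under any
standard d definition; the package documents its pooled-SD definitions
rather than reverse-engineering those numbers. EDF ingest quantizes to 16
bits; BrainVision sessions carry no accelerometer, so onset detection for
them requires an externally attached acceleration trace.
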