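---
title: "Conditioning the N2pc on microsaccades: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditioning the N2pc on microsaccades: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccatt)
```

## The analysis problem

The N2pc — the contralateral-minus-ipsilateral voltage difference at
posterior electrodes PO7/PO8, 200–300 ms after an attention cue — is a
canonical EEG marker of covert spatial attention. Microsaccades made
around the same time show a directional bias toward the attended side.
Because the two co-occur, any N2pc could in principle be an oculomotor
artifact. The discriminating observation is single-trial: microsaccades
are discrete events, so trials can be classified by whether a gaze shift
occurred in a post-cue attention window and in which direction, and the
N2pc examined within each class. A second, sharper probe is temporal:
if the N2pc were a direct consequence of the eye movement (retinal
displacement, muscle activity, corneo-retinal dipole rotation), it would
lock in time to saccade onset in single trials the way the EOG deflection
and the occipital lambda response do; if it reflects the attention shift,
it stays locked to the cue.

`saccatt` implements both probes, plus the statistics used to evaluate
them, and a generator that plants all of these components with known
parameters.

## Detection model

Gaze velocity is the Euclidean distance between successive gaze samples
divided by the sample interval (deg/s); by default only the horizontal
channel enters, matching the left/right task geometry (a `"2d"` mode
combines both axes). Velocity is smoothed with a Gaussian-weighted moving
average over a 7 ms window; the kernel SD follows the
`(window − 1)/5` convention of common gaussian-window smoothers, and
missing samples are excluded with weight renormalization rather than
propagated. A saccade begins at the first sample whose smoothed velocity
exceeds `k × median` of the trial's valid smoothed velocity (default
`k = 3`); the median is taken on the *smoothed* series, and the
refractory rule is interpreted onset-to-onset: a crossing within 100 ms
of an accepted onset is discarded. Direction and magnitude compare mean
position over [−50, 0) ms against [50, 100) ms around onset. Shifts
below 0.05° are too small to ascertain direction; they are retained in
the event table as `sub_minimum` so the classifier can exclude those
trials, and events whose characterization windows are cut off by the
epoch edge or fully missing are marked `unresolved`.

Trial classes follow from the first detected shift in the attention
window, half-open [150, 400) ms (all windows in the package are
half-open, matching the epoch convention [−1000, 1500)): direction
matching the cued side gives *toward*, opposite gives *away*, no
in-window event gives *none*. A trial with any missing gaze sample in
the window is excluded (`missing-data`), and a trial with any
sub-minimum shift in the window is excluded (`sub-minimum-shift`) —
exclusion is triggered by the presence of an unclassifiable shift, not
only when no classifiable shift exists, since an uncertain gaze record
should not be labelled "no microsaccade".

## Lateralized measures

ERP epochs are baseline-corrected over [−250, 0) ms. The contralateral
wave pools the right-hemisphere channel on left-cued trials with the
left-hemisphere channel on right-cued trials (and symmetrically for
ipsilateral); trial-averaged waves are smoothed with a Gaussian kernel of
SD 15 samples with reflective edge padding — reflection avoids edge droop
at the epoch boundaries, and, applied after averaging, smoothing
commutes with the contra−ipsi subtraction. The N2pc amplitude is the
mean difference over [200, 300) ms. Per-participant waves are computed
first; grand averages weight participants equally regardless of trial
counts.

Spectral lateralization uses a Hanning-tapered short-time Fourier
transform: 300 ms segments stepped by 20 ms, powers at 3–40 Hz in 1 Hz
steps. At a 1024 Hz sampling rate a 300 ms segment is 307 samples;
segments are zero-padded to 1024 samples (one second — itself a power of
two) so the FFT grid lands exactly on integer frequencies; padding to
the next power of two above the segment length (512) would give 2 Hz
bins and miss the 1 Hz grid. Power is averaged over trials within each
cued side before forming `L = 100·(contra − ipsi)/(contra + ipsi)` — a
ratio of means, which is stabler than a mean of ratios at realistic
trial counts — and the alpha summary averages L over 8–12 Hz and
400–800 ms. For a planted contra:ipsi amplitude ratio `r` the index is
`100 (r² − 1)/(r² + 1)`, which the tests verify on noise-free input.

## Cluster permutation statistics

Participant-level difference series (condition − 0 or A − B) are tested
pointwise with a one-sample t statistic; samples with two-sided p < 0.05
are grouped into clusters of adjacent same-signed significant samples
(temporal adjacency for time courses, 4-connectivity for
time-frequency maps), scored by the sum of t values. Each permutation
flips each participant's series by an independent ±1 — the exact null
symmetry of a paired design — and records the largest absolute cluster
mass; a cluster's p value is the proportion of permutations whose
maximum reaches its absolute mass. Ties count against the hypothesis,
the identity labelling is not forcibly included (a literal proportion,
so p = 0 is possible and reported as "< 1/n_perm"), and time points with
zero variance have an undefined t and are treated as non-significant but
counted. An exhaustive mode enumerates all 2^n sign patterns for small
n and is checked against an independent enumeration in the tests. The
default 10,000 permutations can be lowered for exploratory runs.

The ANOVA layer is a one-way repeated-measures decomposition (subject
stratum removed) with partial η² = SS_effect/(SS_effect + SS_error) and
no sphericity correction, so k = 3 classes and n = 23 participants give
the familiar df = (2, 44). At k = 2 the F equals the squared paired t,
which the tests assert. Post-hoc tests are two-sided paired or
one-sample t tests with Cohen's d = mean(diff)/sd(diff) and Bonferroni
adjustment over the stated family (m = 3 for the pairwise family).
Response times are trimmed in a fixed order — first RTs above 3000 ms,
then values beyond 2.5 SD of the participant's mean, where mean and SD
are computed over the step-1 survivors pooled across classes (the rule
names the participant, not the class) — and the order is pinned by a
regression test because reversing it changes the result.

## ERP images and the alignment statistic

Toward-microsaccade trials are pooled across participants and tasks,
sorted by saccade latency (stable sort: tied onsets keep input order),
and smoothed first across 10% of neighboring trials in sorted order,
then across a 50 ms time window. The named spans are interpreted as the
full width of a Gaussian kernel with SD = span/4. The order
trials-then-time is pinned by a regression test; with gaps present the
two orders genuinely differ.

The dissociation itself is visual in origin, so the package adds a
quantification: for each smoothed row, the latency of the component
extremum is located inside a search window (150–500 ms by default) and
Spearman-correlated with the sorted onsets, with a 1000-resample
bootstrap CI. Saccade-locked components give ρ near 1, cue-locked
components near 0. Extremum definitions are per derivation: `max` for
the lambda response on Oz, `min` for the N2pc difference, and `slope`
(largest absolute time derivative) for the horizontal EOG — a step
signal has no peak, but its steepest edge marks the saccade. In the
pipeline the HEOG rows are first sign-aligned to the toward direction
(leftward saccades produce negative EOG steps; without alignment,
left- and right-cued rows cancel under trial smoothing).

## The synthetic experiment

The generator emulates the study design the analysis is meant for: 23
participants, two tasks (selection from perception and from working
memory), 600 trials per task, objects at 5° eccentricity left/right,
gaze at 1000 Hz and EEG (PO7, PO8, Oz, HEOG) at 1024 Hz, epochs
[−1000, 1500) ms around the cue.

Per trial, a class label (*toward*/*away*/*none*, probabilities
0.36/0.24/0.40, mirroring the proportions such experiments report) is
drawn. Toward/away trials carry one planted saccade with onset uniform
inside the attention window; none trials carry no in-window saccade.
Background saccades (0.5 Hz, random direction) occur outside the window
identically for all classes, so only the in-window bias separates them.
Saccade displacement is a raised cosine over 20 ms — smooth,
differentiable, and with a clean velocity peak of `mag·π/(2·0.02 s)`,
so a 0.1° saccade peaks near 7.9 deg/s, comfortably above the ≈ 2 deg/s
noise-driven median-based threshold at the default noise. Magnitudes are
uniform on [0.1, 1.0]°: the magnitude distribution is a free parameter
of the generator (reported results only bound it below 1°), and a
uniform draw exercises the size-binning machinery evenly. Drift is a
random walk on a 20 ms knot grid, spline-interpolated, scaled so the
end-of-epoch excursion SD is `drift_sd` (0.1°); white measurement noise
of 0.002° is added, and with probability 0.05 a blink (a 100–300 ms zero
run) is inserted.

The EEG contains, per trial: a Gaussian N2pc bump (SD 15 ms, centered in
the 200–300 ms window) on the channel contralateral to the cue, scaled
so that its *mean over the window* equals the planted class amplitude —
toward −1.5, none −0.5, away 0 µV — plus a per-participant,
per-class offset with SD 0.6 µV representing individual differences; a
saccade-locked EOG step on HEOG (16 µV/°, the conventional corneo-retinal
gain); a lambda bump on Oz (3 µV, SD 15 ms) 125 ms after each saccade
onset; a 10 Hz oscillation at PO7/PO8 with random phase, ramping from
400 ms, with amplitude asymmetry contra `(1 − d)` vs ipsi `(1 + d)`
(d = 0.15); and background noise of 5 µV total SD split equally between
white and 1/f-shaped components — enough structure to exercise the
smoothing and permutation machinery without fitting real spectra.
Behavior is lognormal RT (means ≈ 700–740 ms per class, so all
conditions respond well under a second) and Bernoulli accuracy
(0.89–0.92, above the performance floor such tasks require).

Randomness descends from one master seed through per-trial substreams
derived by integer hashing of (seed, participant, trial, stream), so any
trial regenerates identically regardless of generation order.

What the generator deliberately does **not** emulate: a 64-channel
montage or volume conduction (only the four analysis channels exist, so
topographies reduce to the PO7/PO8 pair), ocular overshoot, pupil
signals, saccade-locked artifacts *on the posterior channels* (the
dissociation between saccade-locked and cue-locked components is planted
by construction — passing tests show the machinery separates them, not
that real brains do), non-stationary noise, or trial-to-trial N2pc
latency jitter. Conclusions about real data rest on the analysis logic,
not on these simplifications.

## Problem sizes and runtime choices

The end-to-end checks run at the sizes the methods are specified for:
the null-calibration check uses 500 simulated datasets of 23
participants × 1500 time points with 1000 permutations each; detector
recovery uses one participant's 1200 trials (≈ 2000 planted saccades);
pipeline recovery runs the full 23 × 1200-trial default; the ERP-image
dissociation uses 6 participants × 300 trials (≈ 630 pooled toward
trials), plenty of rows for the 10% trial kernel. Unit tests use a tiny
3 × 120-trial fixture. Cluster tests inside the pipeline default to
2000 permutations; the headline 10,000 remains the function default.

## Known limitations

- The detector implements the plain median-multiplier threshold, not the
  elliptic (per-axis) variant; binocular conjugacy checks and saccade
  offset/duration estimation are out of scope.
- The 2D mode reports direction as an angle but the classifier consumes
  only the horizontal sign, by design of the lateral task geometry.
- TFR cluster permutation is supported with 4-connectivity but is slow
  for large maps at high permutation counts (the per-permutation
  labelling is plain R).
- `rm_anova()` applies no sphericity correction, deliberately matching
  the uncorrected df = (2, 44) reporting convention; with three levels
  and moderate n this is mildly anticonservative under non-sphericity.
- Paired tests refuse zero-variance differences (the t statistic is
  0/0-undefined there) rather than reporting t = 0.
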