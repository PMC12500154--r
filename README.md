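# saccatt

Covert shifts of visuospatial attention leave two concurrent, lateralized
traces: a posterior EEG deflection — the **N2pc**, the
contralateral-minus-ipsilateral voltage difference at PO7/PO8 around
200–300 ms after an attention cue — and a directional bias in the tiny
fixational eye movements (**microsaccades**, < 1°) made around the same
time. Because microsaccades are discrete single-trial events while the EEG
is continuous, trials can be sorted by whether a microsaccade occurred in
the post-cue attention window and in which direction, and the N2pc can be
examined conditional on that sorting. `saccatt` implements that analysis
chain for researchers in cognitive neurophysiology working with combined
eye-tracking + EEG recordings, and ships a synthetic experiment generator
with planted ground truth so every stage is testable without any data
download.

The pipeline:

1. **Gaze preprocessing** — blinks appear as zero runs in EyeLink-style
   gaze samples; every zero run ±100 ms is set to missing, and gaze is
   epoched −1000..+1500 ms around the cue (`mask_blinks()`,
   `epoch_gaze()`).
2. **Microsaccade detection** — gaze velocity `v[t] = |Δx|·f` (1D
   horizontal, or the 2D step norm) is smoothed with a Gaussian-weighted
   7 ms moving average; samples exceeding a trial-based threshold of
   `3 × median(v)` mark saccades, with a 100 ms onset-to-onset refractory
   rule. Direction and magnitude come from mean gaze position in
   [−50, 0) vs [50, 100) ms around onset; shifts < 0.05° don't count as
   saccades (`detect_saccades()`, `threshold_sweep()`).
3. **Rate dynamics** — toward/away saccade-rate time courses in a 50 ms
   sliding window stepped at 1 ms, and a time × size decomposition of the
   rate bias in 0.2° bins advanced by 0.04° (`saccade_rate()`,
   `rate_by_size()`).
4. **Trial classes** — each trial becomes *toward*, *away* (direction of
   the first detected shift in [150, 400) ms relative to the cued side)
   or *no-microsaccade*; trials with missing gaze or sub-minimum shifts
   in the window are excluded (`classify_trials()`).
5. **Lateralized ERP** — baseline correction over [−250, 0) ms,
   contra/ipsi assembly at PO7/PO8 relative to the cued side, Gaussian
   smoothing (SD 15 samples) of trial-averaged waves, and the windowed
   N2pc amplitude as the mean difference over [200, 300) ms
   (`contra_ipsi()`, `n2pc_amplitude()`).
6. **Spectral lateralization** — Hanning-tapered 300 ms STFT (3–40 Hz,
   1 Hz steps, 20 ms hops) and the bounded index
   `L = 100·(contra − ipsi)/(contra + ipsi)`, summarized over 8–12 Hz and
   400–800 ms (`stft_power()`, `lateralization_index()`).
7. **Statistics** — cluster-based sign-flip permutation tests on
   participant-level time courses (pointwise one-sample t, two-sided
   α = 0.05, cluster mass = Σt, max-mass null over participant-level sign
   flips), one-way repeated-measures ANOVA with partial η², paired /
   one-sample t tests with Bonferroni correction, and two-step RT
   trimming (> 3000 ms, then 2.5 SD) (`permutation_test()`, `rm_anova()`,
   `paired_tests()`, `trim_rts()`).
8. **ERP images** — single-trial HEOG / Oz / N2pc-difference series
   sorted by microsaccade latency, smoothed across 10% of neighboring
   trials then a 50 ms time window, with a Spearman alignment statistic
   quantifying whether each component locks to saccade onset or to the
   cue (`build_erp_image()`, `alignment_statistic()`).

Everything is driven from tibbles and returns tibbles (with light array
containers for epoched EEG and TFR power); fitted objects have
`tidy()`/`glance()` methods and results have `autoplot()`/`plot_*()`
functions.

## Worked example

Simulate a small experiment (8 participants, 200 trials per task; the
generator plants window-mean N2pc amplitudes of −1.5 / −0.5 / 0 µV for
toward / none / away trials) and run the pipeline:

```r
library(saccatt)
cfg <- sim_config(n_participants = 8, trials_per_task = 200, seed = 42)
res <- run_pipeline(cfg, stages = c("erp", "stats"))

res$proportions$summary
#>   class   mean      se
#> 1 away   0.226 0.00712
#> 2 none   0.397 0.0107
#> 3 toward 0.377 0.0118

per_p <- res$amplitudes |>
  dplyr::group_by(participant, class) |>
  dplyr::summarise(amp = mean(amplitude), .groups = "drop")
dplyr::group_by(per_p, class) |>
  dplyr::summarise(mean_uV = mean(amp), se = sd(amp) / sqrt(dplyr::n()))
#>   class  mean_uV    se
#> 1 away    -0.499 0.257
#> 2 none    -0.478 0.196
#> 3 toward  -1.39  0.286

res$anova$perception
#> One-way repeated-measures ANOVA: F(2, 14) = 5.931, p = 0.01362, partial eta^2 = 0.459

paired_tests(per_p, list("toward", "none", "away"), m = 1, value = "amp")
#>   comparison     t    df      d       p
#> 1 toward - 0 -4.86     7 -1.72  0.00184
#> 2 none - 0   -2.43     7 -0.860 0.0452
#> 3 away - 0   -1.95     7 -0.688 0.0927
```

Reading this: the detector/classifier recovers the planted trial mix
(≈ 38% toward, 23% away, 40% none); the N2pc is largest with toward
microsaccades (−1.39 µV, clearly below zero), small but detectable
without microsaccades, and not established on away trials — the
qualitative dissociation the pipeline is built to expose. At the default
full scale (23 participants × 1200 trials) the same chain recovers the
planted amplitudes within two standard errors and yields the
`F(2, 44)` repeated-measures layout; see `tests/testthat/test-acceptance.R`.

## Vignette

`vignettes/microsaccades-n2pc.Rmd` documents the model assumptions, the
synthetic-data design (what it emulates and what it deliberately does
not), all tunable parameters with units and defaults, numerical choices,
and known limitations.
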