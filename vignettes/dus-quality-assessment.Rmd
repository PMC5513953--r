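---
title: "Template-based quality assessment of 1-D Doppler ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based quality assessment of 1-D Doppler ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

One-dimensional Doppler ultrasound (DUS) of the fetal heart is an audio-band
signal whose frequency content encodes the velocity of cardiac structures:
valve snaps appear as short broadband bursts, wall motion as energy in the
few-hundred-hertz range. Recordings made with low-cost transducers by
minimally trained operators vary enormously in quality, and every metric
derived from them (heart rate, rhythm, valve timing) inherits that
variability. `dusqi` implements an automated per-segment quality score so
that poor recordings can be flagged at acquisition time or filtered
retrospectively.

The core idea is *self-consistency*: in a clean recording the envelope of
consecutive cardiac cycles is highly repeatable, so a cycle should correlate
strongly with a running template built from its neighbours. Noise,
transducer movement and dropouts destroy that repeatability long before they
change summary statistics like total power.

## Pipeline

1. **Ingest and resample** (`load_recording()`,
   `resample_to_working_rate()`). Audio is taken to a 4 kHz working rate
   through a least-squares linear-phase FIR anti-aliasing filter. Fetal
   cardiac content lies well below the 2 kHz Nyquist of the working rate.
2. **Beat detection** (`sift()`, `select_optimal_imf()`,
   `detect_beats()`). Each 4-s window (3-s hop, 1-s overlap) is decomposed
   by empirical mode decomposition; for each of the first four intrinsic
   mode functions an amplitude envelope is drawn through the IMF's peaks,
   and the IMF whose envelope peaks recur most regularly — minimum standard
   deviation of the peak-to-peak intervals — is chosen as the beat carrier
   for that window. Per-window peaks are stitched across the 1-s overlaps,
   sub-physiological intervals (above 210 bpm, typically the second valve
   event of the same cycle) are removed, and a sliding 5-interval rule
   replaces any interval deviating more than 20 % from the mean of its four
   neighbours.
3. **Cycle envelopes** (`cwt_valve_band()`, `cycle_envelopes()`). The
   signal is convolved with an order-2 complex Gaussian wavelet at a single
   scale tuned to the sub-kHz valve/wall band; the magnitude envelope is
   interpolated through its maxima, low-pass smoothed, cut at beat onsets,
   and each cycle normalized to zero mean and unit variance.
4. **Templates and SQIs** (`build_templates()`, `compute_beat_sqis()`).
   Every 15-s window gets a template of length `L` = rounded mean
   beat-to-beat interval, first as the plain cycle average and then updated
   from only those cycles correlating at `r >= 0.6`; a window where fewer
   than 20 % of cycles reach that gate inherits the previous (else next)
   window's template. Each beat is scored four ways against its template —
   directly (truncation / tail zero-padding), after linear resampling to
   `L`, after dynamic time warping, and after phase-weighted DTW — with
   negative correlations clipped to zero.
5. **Segment features** (`build_feature_vector()`). 3.75-s segments on a
   3-s stride take the median of each SQI over their beats, plus sample
   entropy (`m = 2`, `r = 0.1 x SD`) of the raw segment and the fraction of
   spectral power in the 160–660 Hz Doppler band.
6. **Classification** (`bootstrap_cv()`, `train_quality_svm()`). An RBF
   SVM separates good from poor segments; validation is subject-stratified:
   subjects are partitioned into five folds, 60 segments per class per fold
   are drawn with replacement, hyperparameters come from an inner five-fold
   grid search on the training sample, features are normalized with
   training-fold statistics only, and the whole procedure is repeated with
   re-randomized folds, summarized by medians.

## Tunable parameters

All knobs live in one `dus_config()` object; the important ones:

| key | default | meaning |
|---|---|---|
| `target_fs` | 4000 Hz | working rate |
| `seg_len_s` / `seg_stride_s` | 3.75 / 3 s | segment grid |
| `emd_sd_stop` | 0.2 | sifting convergence (normalized envelope-mean energy) |
| `imf_env_smooth_hz` | 15 Hz | IMF-envelope smoothing before peak regularity scoring |
| `cwt_scale` | 8 samples | wavelet scale; centre response near 300 Hz at 4 kHz |
| `smooth_cutoff_hz` | 25 Hz | cycle-envelope smoothing |
| `envelope_fs` | 200 Hz | storage rate of the smoothed envelope |
| `bpm_min` / `bpm_max` | 90 / 210 | physiological interval gate |
| `corr_threshold` / `validity_fraction` | 0.6 / 0.2 | template update gate |
| `wdtw_g` | 0.02 | logistic phase-penalty steepness |
| `entropy_m` / `entropy_r_frac` | 2 / 0.1 | sample-entropy parameters |
| `psd_band` | 160–660 Hz | Doppler power band |
| `c_exponents` / `sigma_exponents` | −3…5 / −5…2 | base-2 SVM grids |

## Design choices worth knowing about

**Sifting stop.** A candidate component is accepted when the energy of its
envelope mean falls below `emd_sd_stop` relative to the component *and* the
defining extrema/zero-crossing balance holds. The energy criterion alone can
stop while riding waves remain (violating the IMF definition); requiring the
count balance fixes that. Convergence is tested *before* the subtraction, so
a sequence that already is an IMF passes through unchanged — decomposition
is exactly idempotent on its own output.

**Envelope peaks, not raw peaks.** For IMF selection the envelope is
low-passed at 15 Hz (zero phase) and envelope peaks below the mean envelope
level are ignored. Without this, spline-envelope wiggle at the noise floor
produces a dense comb of spurious peaks whose spacing is set by the
interval gate rather than the heart; with it, envelope peaks land on the
valve-event bursts.

**Two bursts per cycle.** DUS cycles carry two valve events, so the
envelope-peak train runs at roughly twice the heart rate with alternating
short/long gaps. The minimum-interval gate (210 bpm) removes the second
burst of each pair deterministically (keeping the earlier event), which is
what makes the detected "beats" cycle onsets.

**Envelope rate.** The smoothed envelope is band-limited at 25 Hz, so it is
stored at 200 Hz (8x oversampled). Template lengths become ~60–110 samples
instead of ~1200–2200, which shrinks the DTW dynamic program by two orders
of magnitude without changing any correlation; a template at the full rate
can be recovered by setting `envelope_fs = target_fs`.

**"Scale 3".** The third dyadic scale (2^3 = 8 samples) of the complex
Gaussian mother at 4 kHz concentrates the response near 300 Hz with support
below 1 kHz, matching fetal wall velocities; a literal scale value of 3 can
be configured via `cwt_scale` but centres far above the band of interest.

**SQI2 source interval.** The linearly resampled SQI stretches the *full*
beat-to-beat envelope to length `L` (configurable to the L-clipped excerpt
via `sqi2_mode`); the direct and DTW variants score the onset-aligned
excerpt, zero-padding only when a cycle is shorter than `L`.

**Weighted DTW.** The phase weight is the modified logistic
`w(d) = 1 / (1 + exp(-g (d - L/2)))` with `d = |i - j|`. Note that `g`
rescales the weights globally: the monotone quantity as `g` grows is the
optimal cost *relative to the in-phase weight* `w(0)`, not the raw cost. At
`g = 0` all weights are equal and the weighted SQI coincides with plain DTW.

**Probability calibration and threshold.** libsvm's internal probability
machinery draws from an RNG the caller cannot seed, so the package fits its
own logistic (Platt-style) map from decision values to `p(good)` and picks
the probability threshold maximizing balanced accuracy on the training set.
Both live in the saved model record; the threshold is data-derived, not a
constant of the method.

**Hyperparameter grids.** The printed exponent sets for `C` and sigma are
not arithmetic sequences, so both lists are configuration (`c_exponents`,
`sigma_exponents`), defaulting to {−3, −1, 1, 3, 5} and {−5, −2, 1, 2}.
Ties prefer the smallest `C`, then the largest sigma.

**Tie-breaks.** Equal PPI-SD: lowest IMF index. Equal band-search distance:
widest band, then lowest low edge. Subject ranking ties: lexicographic id.
The last subject in the alternating train/test split joins the side with
the smaller running segment total.

## The synthetic generator

Clinical DUS recordings cannot ship with the package, so `synth_recording()`
emulates their statistics at 4 kHz: Gaussian-jittered cycle lengths around a
mean fetal heart rate (default 140 ± 3.5 bpm, a normal mid-gestation rate
with typical short-term variability), two Gaussian-windowed bursts of
160–660 Hz band-limited noise per cycle (the second 30 % weaker, at 40 % of
the cycle), additive broadband noise at a chosen SNR, and optional dropouts
and low-frequency transients. Three simulated annotators threshold a shared
per-second latent quality score with offset thresholds, which produces
unanimous labels at SNR extremes and the intermediate consensus classes
(mostly clean / mostly noisy) near the crossover.

What the generator does *not* model: insonation-angle physics, fetal
movement Doppler shadows, maternal vessel interference, transducer-specific
frequency responses, or annotator biases beyond a threshold offset. Passing
tests on synthetic data therefore demonstrate the pipeline's mechanics —
beat recovery, template dynamics, feature separability, validation hygiene —
not clinical-grade accuracy on real recordings.

## Numerical notes

- Degenerate inputs: zero-variance cycles are dropped; zero-variance
  segments give sample entropy 0 (with a warning) and PSD ratio 0; a cycle
  with zero variance after trimming scores 0 on every SQI.
- When no length-`m+1` entropy match exists, the value is capped at
  `log(B (N - m - 1))` to stay finite.
- Sample-entropy pair counting uses a sorted first-coordinate prefilter;
  the counts are exactly those of the quadratic scan (verified in the test
  suite against a naive oracle).
- The anti-alias FIR is designed by least squares over passband and
  stopband grids with the transition band unconstrained; the truncated-sinc
  alternative has Gibbs ripple that measurably distorts passband tones.
- Spline envelopes mirror the two nearest extrema about each signal end.

## Validation scale

The test suite and the acceptance script size their simulations for a
single CPU: 60-s recordings, cohorts of 8 subjects x 2 recordings for
classifier validation, 20 bootstrap repetitions (the `n_reps` default of
100 matches the method's reference design and is what we recommend for real
studies), and 10 recordings for beat-recall measurement. At these sizes the
full validation runs in minutes; all quantities are seeded and
reproducible.

## Limitations

- Beat detection assumes quasi-periodicity in a 90–210 bpm band; sustained
  arrhythmia or signal loss longer than a template window defeats the
  fallback chain, and such windows score 0.
- Templates are strictly per-recording and per-window; there is no
  cross-subject template library.
- The classifier is trained on unanimous (good/poor) segments only;
  intermediate classes are assessed, never trained on.
- Sample entropy is computed on the raw audio segment (configurable), not
  on a demodulated envelope; the two choices are not interchangeable and
  the default follows the method's reference design.
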