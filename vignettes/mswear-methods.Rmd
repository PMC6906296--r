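---
title: "Biosensor disability features in MS: models, extractors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biosensor disability features in MS: models, extractors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mswear)
```

`mswear` turns raw body-worn sensor streams — tri-axial acceleration
(m/s²), angular velocity (deg/s), and inter-beat intervals (ms) — into the
mobility, balance, activity, sleep and fatigue features that track
neurologist-rated MS disability, and correlates them with EDSS and the
MSFC-4 composite. This vignette documents the signal models, the
extractor algorithms and their tunable parameters, the synthetic cohort
the package validates itself against, and the numerical choices and
limitations a user should know about.

## Conventions

Time is seconds since recording start, on the device clock; annotations
share that clock (a single-clock assumption — no cross-device
synchronisation is modelled). Gyroscope units are deg/s on disk and
internally, so turn angles integrate directly to degrees. Missing samples
are encoded by timestamp gaps, never sentinel values; a gap of more than
two nominal sample periods splits a contiguous segment. Task windows use
half-open `[start, end)` sample inclusion.

## Gait: stance and swing from ankle sagittal angular velocity

During walking the ankle's sagittal angular velocity is near zero in
stance and shows one large, smooth positive pulse per swing. The detector
(`detect_gait_events()`) works in two stages:

1. **Mid-swing peaks** are found on a 0.5–6 Hz band-passed copy
   (4th-order zero-phase Butterworth): local maxima above
   `peak_thresh_deg_s` (default 40 deg/s) separated by at least
   `min_peak_sep_s` (0.4 s).
2. **Toe-off and heel-strike** are the last upward and first downward
   crossings of `onset_thresh_deg_s` (10 deg/s) around each peak. These
   are localised on a *low-passed* copy (default cutoff 12 Hz, capped at
   0.45·fs), not the band-passed one: the 0.5 Hz high-pass removes the DC
   of the pulse train and would push the stance baseline below zero,
   biasing every crossing. Each crossing is then projected to the
   baseline assuming a locally quadratic onset
   (`t₀ = t − 2y/ẏ`, exact for any pulse that rises quadratically, as a
   raised cosine does), clamped to 80 ms and to the correct direction.

Stance of stride *i* is `toe_off(i+1) − heel_strike(i)`; swing is
`heel_strike(i) − toe_off(i)`; stride = stance + swing by construction.
Session and daily summaries use **medians** over strides, which is what a
free-living aggregate needs (robust to occasional missed or spurious
events). With the defaults, noise-free synthetic bouts across stride
rates 0.6–1.2 Hz and stance fractions 0.55–0.70 are recovered with exact
step counts and stance errors below two sample periods; with 10 deg/s
additive noise the median stance error stays below 5 ms at 100 Hz.

Left and right streams are processed independently; the device body
location identifies the foot. Table-style summaries pool both ankles.
"Mobility activity time" is interpreted as the duration of the mobility
task window (for a TUG, the time to complete the test); the measurement
protocol does not pin this definition down further.

## Turns: yaw-rate integration

`detect_turns()` low-passes the yaw rate at 1.5 Hz (zero phase), seeds
candidate regions where |yaw| > 15 deg/s, expands them outward to the
5 deg/s crossings, merges gaps under 0.2 s, and discards events whose
integrated angle is below 45°. The **angle is trapezoid quadrature of the
raw, unfiltered yaw over the detected span**, so filtering cannot bias
it; the peak velocity is likewise read from the raw trace. Mean velocity
is |angle|/duration by default (`mean_mode = "mean_abs_yaw"` switches to
the time-average of |yaw|).

Two numerical consequences are worth knowing. First, a zero-phase filter
smears step edges symmetrically, so for an abrupt (square) yaw pulse the
detected span slightly exceeds the true duration and the mean velocity is
correspondingly low — the angle and peak are unaffected. Second, the
across-turn summary (`summarize_turns()`) defines "max/mean/std" of turn
velocity as the mean of per-turn peaks, the mean of per-turn means, and
the *population* standard deviation of per-turn means: a single turn
cannot yield a spread, and a session has at least three TUG turns.

The yaw axis per body location is the gyro channel aligned with the body
vertical (device z for an upright chest unit), overridable in
configuration; axis conventions are otherwise undocumented for this class
of device.

## Balance: postural sway over the 30-s standing window

`compute_sway()` accepts either a 2-D displacement track (mm) or raw
horizontal acceleration. The two paths exist deliberately: displacement
input admits exact analytic tests (a sinusoid of amplitude A and
frequency f travels 4·A·f·T per axis), while the acceleration path is
the realistic sensor route — gravity estimated as the window-mean
acceleration vector, mediolateral/anterior-posterior axes built from the
horizontal projection of the device axes, 0.1–2 Hz zero-phase band-pass,
then double trapezoid integration with a **linear detrend after each
integration** for drift control (simpler and easier to reason about than
high-passing the displacement; cutoffs documented above). Metrics are the
per-axis path length Σ|Δx| ("sway distance") and max−min excursion
("sway displacement"); path length is 1-D per axis, not the 2-D
trajectory length. The integration path recovers the path length of a
known sinusoid within 10%; the range statistic is more sensitive to edge
effects of the filter/integration chain and carries a looser (20%)
contract in the tests.

## Free-living: activity classification and daily aggregates

Five-second windows of the wrist stream yield accelerometer-magnitude
mean/variance, signal-magnitude area, the dominant frequency of the
gravity-removed magnitude (searched over 0.3–5 Hz, slightly wider than
the decision bands so band-edge stride rates are still localised), a
periodicity score (power fraction at the dominant bin ± 1), and gyro RMS.
The classifier is a transparent threshold rule over those features —
variance below 0.05 (m/s²)² → idle; dominant frequency in 0.6–1.4 Hz
with periodicity > 0.25 → walking; 1.4–3.5 Hz with high magnitude →
running; else other — followed by a 3-window majority vote, with
contiguous windows merged into bouts. It deliberately replaces a trained
classifier: the downstream analyses need only the labels, and a
documented rule is testable against a planted schedule (≥ 90% window
accuracy across seeds on the synthetic days; this is a contract about the
stand-in, not a claim about any production classifier).

Walking bouts are handed to the same gait/turn extractors as the clinic
path. Daily aggregates require at least 10 strides for a gait median
(medians over fewer are unstable); idle minutes come from bout durations;
wear time counts windows whose accelerometer variance exceeds a noise
floor or whose gyro is active. Compliance against a weekly wear target
uses three groups — low (mean weekly wear < 20% of target), declining
(first-two-week mean ≥ 80% and final-two-week mean ≤ 60%), high (≥ 80%
in all but at most two weeks) — with precedence low > declining > high
and unmatched patterns reported as declining.

## Sleep and fatigue

Inter-beat intervals during tagged sleep are cleaned by an ectopic filter
(outside 300–2000 ms, or > 20% off an 11-beat running median) and cut
into 5-min epochs (≥ 30 beats each) carrying mean IBI, SDNN and RMSSD.
Epoch length and feature choice are a documented package decision — the
original trained staging model's inputs are unpublished. The REM/NREM
rule is a fixed threshold: an epoch is REM when RMSSD exceeds
`REM_RMSSD_THRESHOLD_MS` (30 ms — the geometric mean of the night
generator's default stage scales, 45 ms REM vs 20 ms NREM; set once from
those defaults, never refit), followed by a 3-epoch majority vote. On
synthetic nights with that default separation the estimate lands within
±5 percentage points of the scheduled REM fraction. REM% from heart-rate
variability is a proxy, not polysomnography; the same caveat applies to
any conclusions drawn from it.

Leg movements during tagged sleep are excursions of a 0.3-s RMS envelope
of the 0.5–10 Hz band-passed acceleration magnitude above 0.1 m/s²
lasting ≥ 0.5 s, with a 5-s refractory period (the envelope makes an
oscillatory burst one sustained event rather than a train of half-cycles).
PVT features exclude false starts and report the mean delay overall and
over the first 1, 3, 5 and 7 valid challenges. The daily fatigue
questionnaire is carried in the data model but has no bespoke
computation.

## Statistics

MSFC-4 z-scores are referenced to this cohort at its baseline visit (the
classic choice when no external reference population is named; an
external reference is accepted). Timed tests enter negated so higher
always means better; the 9HPT can enter either as a negated time z-score
(default, symmetric with T25FW) or as the z of 1/time (the classic rate
form) — both conventions are implemented behind `nhpt_mode` because the
exact convention is ambiguous in this setting. The composite is the mean
of the four subtest z-scores.

Spearman correlations are Pearson correlations of midranks; the two-sided
p-value uses the t-approximation with n−2 degrees of freedom, which
reproduces the published worked values at n = 23 to their printed
precision. Storey q-values estimate the null proportion on the grid
λ = 0, 0.05, …, 0.90 with a cubic smoothing spline evaluated at the grid
top, clipped into (0, 1]; forcing π̂₀ = 1 reduces exactly to
Benjamini–Hochberg (verified against a brute-force oracle). The
multiple-testing family is **one clinical measure × all features** —
matching per-column significance marking of a feature-by-measure table.
Both p- and q-based significance flags are reported at 0.05 and 0.01
because it is ambiguous whether published starring thresholds the two
jointly or separately.

`variability_vs_days()` quantifies how aggregation stabilises a daily
median: for each window length k it resamples contiguous k-day blocks,
takes each block's median, and reports the RMS deviation from the
full-period median. On independent daily values the curve falls with k
(the median concentrates); the package checks the one-week-versus-one-day
contrast per subject.

## The synthetic cohort

`subject_profiles()` draws a latent disability d ~ Uniform(0, 1) per
subject and derives every true parameter through monotone effect
functions: stance time 0.55 + 0.35·d s, peak turn velocity 220 − 120·d
deg/s, sway amplitudes 1 + 6·d mm, REM fraction 0.25 − 0.10·d, idle
fraction 0.40 + 0.30·d, PVT delay 250 + 150·d ms, and MSFC-4 subtest
scores with matching signs. EDSS is a quantile map of d onto the
half-step grid 1.0–6.5 (ordinal, spanning a moderate-disability cohort).
The magnitudes are plausible values for an MS cohort, labelled synthetic,
and not calibrated to any real dataset — with one exception: the
between-subject noise levels are set so that the population Spearman
correlation between stance time and the MSFC-4 composite is ≈ −0.6, a
deliberately planted effect size the pipeline must recover. With
`noise_scale = 0` every feature–disability correlation is exactly ±1.

Signals are built from raised-cosine pulses (swing, turn) because they
are smooth, band-limited and analytically integrable — every extractor
has a closed-form oracle. Sway tracks come either as quadrature-phase
sinusoids (analytic) or low-passed Gaussian walks (realistic spectrum);
displacement is emitted directly and acceleration derived on demand,
since the balance extractor supports both inputs. Nights are AR(1) IBI
processes around stage means with stage-specific short-term variability.
Clinic IMU noise defaults to 3 deg/s additive Gaussian.

What the generator does **not** emulate: 3-D limb kinematics, soft-tissue
and mounting artefacts, heteroscedastic sensor noise, real activity
diversity (stairs, cycling, carrying), arrhythmias in the IBI stream, or
any waveform-level PPG content. Passing recovery tests on this cohort
therefore demonstrates internal consistency of the pipeline — that each
extractor inverts the documented signal model at the planted effect
sizes — not field accuracy on clinical data.

Free-living days are generated on demand (deterministically from the
master seed, per subject and day) rather than materialised with the
cohort: a full cohort of day-long raw streams would be needlessly large.
Each simulated day is a condensed monitored window (default 30 min at
20 Hz in analyses, scalable) scheduling idle/walking/other segments with
the subject's idle fraction, a per-day stance wobble of 0.02 s, and the
ankle swing-pulse signal inside walking segments.

## Problem sizes and determinism

Every stochastic function takes a seed, and sub-seeds are derived with a
small-multiplier integer hash kept below 2³¹, so cohorts, days and runs
are exactly reproducible (`ms_run()` writes an md5 manifest; two runs of
the same config are byte-identical). The package's own validation uses:
100 replicate 23-subject cohorts (40 Hz clinic streams, three TUGs plus a
15-s walk test) for the planted-sign recovery study; 100 seeded gait
bouts, 50 turn sessions and 50 synthetic nights for the signal oracles;
and 56-day daily series for the variability contrast. These sizes were
chosen to exercise the estimators well past their asymptotic wobble while
keeping a full validation run in minutes on a laptop.

## Known limitations

* Event-timing resolution after sub-sample onset projection is ~1 ms;
  two subjects whose true stance times differ by less cannot be ranked
  reliably, so exact rank recovery on noise-free cohorts holds only when
  subjects are separated by more than that resolution.
* The activity classifier and REM rule are transparent stand-ins; their
  accuracy contracts apply to the synthetic signal models only.
* No stride length, walking speed, or sensor-fusion orientation
  estimation; no center-of-pressure or frequency-domain posturography;
  no automatic sleep detection (sleep comes from tags).
* Turn duration (and hence mean velocity) is biased long for abrupt
  pulses by the zero-phase detection filter; angle and peak are not.
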