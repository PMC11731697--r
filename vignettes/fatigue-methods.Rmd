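---
title: "Detecting calf muscle fatigue from wearable sEMG and plantar pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting calf muscle fatigue from wearable sEMG and plantar pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Localized muscle fatigue has two accessible, complementary signatures in
wearable recordings. First, fatigue slows muscle-fiber conduction
velocity, which compresses the surface electromyogram (sEMG) power
spectrum toward lower frequencies; the standard scalar summary is the
**median frequency (MDF)**, the frequency that splits the spectrum into
two halves of equal total power. A pre-to-post downward MDF shift is the
accepted marker of localized fatigue. Second, when the calf
(gastrocnemius) fatigues, push-off weakens and body load migrates from
the forefoot toward the heel; insole pressure sensors at six anatomical
regions per foot — hallux (HA), lesser toes (LT), first and fifth
metatarsal (M1, M5), arch, and medial heel (MH) — see this as a decrease
in forefoot peak pressure and an increase under the heel.

`gaitfatigue` implements both analysis arms and the paired pre/post
statistics, plus a synthetic-data generator that emulates the wearable
device's signals, so every stage of the pipeline is testable end to end
without hardware or any external download.

## sEMG arm

Each trial is processed as

1. **Bandpass filter**: 20–500 Hz windowed-sinc (Hamming) FIR. The order
   is `4 * rate / low` rounded to even (400 at 2000 Hz), giving a
   transition band narrow enough that attenuation at 10 Hz and at
   600 Hz exceeds 40 dB while passband ripple stays well under 1 dB.
   The symmetric kernel is applied in two centered passes with edge
   reflection — the forward–backward scheme — so the filter is exactly
   zero-phase and the effective magnitude response is squared.
2. **Power spectrum**: Welch's method, 1-second Hann segments with 50%
   overlap. Welch averaging trades frequency resolution (1 Hz bins) for
   variance reduction, which stabilizes MDF on stochastic signals; a
   plain single-window periodogram is available via
   `power_spectrum(method = "periodogram")`. Both estimators are
   normalized so summed one-sided power equals the time-domain mean
   square (for Welch, the averaged spectrum is rescaled to the signal's
   exact total power — a pure scale factor that cannot move the MDF).
3. **Median frequency**: the smallest bin frequency whose cumulative
   power reaches at least half the total. The convention is discrete —
   no interpolation between bins — and ties resolve deterministically
   toward the lower frequency. Both split inequalities (cumulative power
   strictly below the MDF bin ≤ half; through it ≥ half) are asserted
   property-style in the test suite.
4. **Trial aggregation**: the three consecutive trials of a condition
   are averaged *at the MDF level* (mean of per-trial MDFs). The
   protocol description does not pin down whether signals, spectra, or
   MDFs were averaged; MDF-level averaging keeps each trial's Parseval
   identity intact and is the default, with spectrum-level averaging
   available (`aggregate = "spectrum"`).

One wording ambiguity deserves note: the protocol describes an sEMG
"envelope" obtained by bandpass filtering. A true envelope
(rectification + low-pass) would distort the very spectrum whose median
is the fatigue index, so the default analyzes the filtered raw signal;
`rectify = TRUE` provides the literal reading for comparison.

## Plantar-pressure arm

No step-segmentation rule is published for the device, so the package
uses relative-threshold crossing: samples above `threshold_frac` (0.2)
times the channel's global maximum form candidate stance intervals, and
intervals separated by less than `min_separation_s` (0.4 s) merge. The
relative threshold makes detection invariant under uniform sensor
scaling, which the suite asserts as a property. Each step's peak is its
interval maximum; peaks are pooled across steps and trials before
averaging (`pooling = "trials"` gives the per-trial-mean alternative).
Pooling maximizes the per-subject sample at the study's n = 12 scale.
Regions yielding no steps are skipped with a warning and excluded — the
pipeline never fabricates zeros. Step intervals are half-open
`[start, end)`; indices are 1-based as is idiomatic in R (the CSV
exchange format carries time in seconds, so nothing observable depends
on the index base).

## Statistics

Pre/post inference is a **paired t-test** computed from its closed form:
`t = mean(d) / (sd(d) / sqrt(n))` with `d = post − pre`, n−1 SDs
throughout, and a two-sided p from the t distribution with n − 1 df.
Twelve regional comparisons and four muscle comparisons are reported at
α = 0.05 with **no multiplicity correction**, matching the original
analysis; Holm correction is available but off by default. Zero
difference variance raises a typed error instead of returning an
infinite t, which surfaces pathological (e.g. constant-shift) synthetic
inputs. Borg RPE scores (6–20) get a descriptive mean/SD summary.

The t p-value is validated two ways in the tests: against a numerically
integrated t density, and against an exact sign-flip permutation oracle.
The permutation comparison is restricted to *non-extreme* cases, defined
as permutation p inside (0.05, 0.95) with no single squared difference
carrying ≥ 30% of the total: when one difference dominates, the discrete
sign-flip null becomes bimodal and no continuous reference distribution
tracks it within the 0.05 comparison band — a property of the oracle at
n ≤ 10, not of the implementation.

## The synthetic world

The generator's defaults are the study's stated conditions: 12 subjects,
3 trials per condition, sEMG at 2000 Hz, pressure at 100 Hz, 1 step/s
cadence.

* **sEMG** is flat band-limited Gaussian noise, chosen because its
  spectral median is closed-form at `(low + high)/2` — an exact
  acceptance surface. Bands are set so the analytic pre-fatigue medians
  equal the reported gastrocnemius MDFs (93.6 Hz left → band 20–167.2 Hz;
  81.3 Hz right → 20–142.6 Hz). Fatigue lowers the band's upper edge,
  keeping 20 Hz fixed, so the median drops by the reported amounts
  (−7.5 / −9.2 Hz); the rectus femoris band (20–160 Hz, median 90 Hz —
  no numeric reference values exist for it, so the band is a
  modeling choice) is unshifted. A 1/f-shaped option exists for realism
  but has no closed-form median and is not used in calibrated tests.
* **Pressure** channels are half-sine stance bursts (duration
  `0.6 / cadence`) with region-specific onsets mimicking heel-to-toe
  roll-off (MH 0 ms, arch 80 ms, M1/M5 160 ms, HA/LT 240 ms at 1 step/s,
  scaled with cadence — a convention, not an empirical claim). Pre
  means use the reported values where available (HA 900.7/883.2, LT
  435.6/325.8, MH 1265.5/1343.4 gf); M1/M5/arch have no reported
  reference values, so plausible mid-range values (1100/500/300 gf) with
  identity fatigue factors stand in. Fatigue multiplies each region's
  mean by the factor implied by its reported percent change (HA 0.680 L /
  0.674 R, LT 0.661 L / 0.687 R, MH 1.110 L / 1.072 R, others 1).
* **Heterogeneity**: subject-level log-normal multipliers (mean 1) with
  CV 0.35 on region means — the reported between-subject SD/mean ratios
  are 0.3–0.45 — and additive Gaussian MDF offsets with SD 15 Hz, the
  order of the reported MDF SDs (22.8/15.5 Hz), kept small enough that
  every subject's band stays inside the 20–500 Hz filter. Per-step
  amplitude noise has CV 0.10, a modeling choice (the protocol reports no
  trial-to-trial figures). Amplitudes truncate at zero and multipliers
  are log-normal, so pressures remain non-negative.

All randomness flows from the single config seed; two runs with equal
configs are bit-identical, which the suite asserts.

What a green synthetic test does *not* establish: the generator has no
sensor noise floor, no crosstalk between regions, no cadence drift, no
double-support overlap, and its sEMG is stationary within a trial
(real fatigue develops during exercise, not between two stationary
states). Green tests establish that the pipeline recovers what it is
pointed at — spectral medians, peak amplitudes, paired effects — at the
stated effect sizes and noise levels, not that the device would.

## Numerical choices and degenerate inputs

* MDF ties break toward the lower frequency; the split property is the
  definition, so it is asserted for every computed MDF.
* The Welch segment falls back to the whole signal when shorter than
  1 s; spectra need ≥ 256 samples.
* All-zero signals are a degenerate-spectrum error for the sEMG arm and
  an empty (not erroneous) step set for the pressure arm — the first is
  unanalyzable, the second is an honest "no steps".
* Filter edges are handled by signal reflection; tests measure passband
  and stopband RMS on the interior to exclude the transient.
* Pressure values are carried in gram-force (gf) as reported by the
  device; no conversion to pascals is attempted because the sensor
  calibration is not described.

## Known limitations

Six-region insoles cannot localize mid-foot pressure finely; the paired
t-test assumes approximately normal subject-level differences (defensible
for means over ~30 pooled step peaks, asserted by simulation at the null
where the type-I rate sits inside binomial bounds of 0.05); and the MDF
convention returns bin frequencies, so its resolution is the spectral bin
width (1 Hz at the default Welch settings).
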