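# gaitfatigue

Detects localized calf-muscle fatigue from two wearable-sensor
modalities and tests whether fatigue redistributes foot loading:

* **sEMG median frequency (MDF).** Surface EMG from the gastrocnemius
  and rectus femoris (2000 Hz) is bandpass filtered (20–500 Hz FIR,
  zero-phase), its power spectrum estimated by FFT (Welch), and
  summarized by the median frequency — the frequency `MDF` satisfying

  `sum_{j <= MDF} P_j = sum_{j >= MDF} P_j = (1/2) sum_j P_j`

  where `P_j` is the spectral power in bin `j`. A pre-to-post *downward*
  MDF shift marks localized muscle fatigue.
* **Plantar peak pressure.** Insole pressure (100 Hz) at six regions per
  foot — hallux (HA), lesser toes (LT), first/fifth metatarsal (M1, M5),
  arch, medial heel (MH) — is segmented into gait steps by relative
  thresholding; per-step peak pressures are pooled over three trials and
  averaged per region. Calf fatigue shows up as forefoot (HA, LT)
  decreases and heel (MH) increases.
* **Paired statistics.** Closed-form paired t-tests
  (`t = mean(d)/(sd(d)/sqrt(n))`, `d = post − pre`, df `n − 1`,
  two-sided, α = 0.05, no multiplicity correction) per region and
  muscle, plus Borg 6–20 RPE summaries.

A synthetic-data generator emulates the whole protocol — band-limited
sEMG noise with a controllable spectral median, half-sine gait bursts
with a forefoot→hindfoot fatigue operator, subject-level heterogeneity —
so the pipeline is fully testable without hardware. Its defaults encode
the study conditions it emulates: 12 subjects × 2 conditions × 3 trials,
prefatigue gastrocnemius medians 93.6 / 81.3 Hz shifting by −7.5 /
−9.2 Hz, and regional fatigue factors taken from the reported percent changes
(HA ≈ 0.68, LT ≈ 0.66–0.69, MH ≈ 1.07–1.11).

## Worked example

```r
library(gaitfatigue)

# one synthetic sEMG trial whose analytic spectral median is 93.6 Hz
sig  <- generate_semg(10, 2000, band = c(20, 2 * 93.6 - 20),
                      seed = 11, label = "emg_L_GA")
filt <- bandpass_fir(sig)                # 20-500 Hz zero-phase FIR
median_frequency(power_spectrum(filt))
#> [1] 96

# full pipeline on a default synthetic cohort
cfg <- synthetic_config(seed = 7)
coh <- generate_cohort(cfg)              # 12 subjects x 2 x 3 trials
res <- analyze_cohort(coh)
res$results[res$results$label %in%
            c("prs_R_HA", "prs_L_MH", "emg_L_GA", "emg_L_RF"), ]
#>     label pre_mean post_mean percent_change  t_stat  p_value significant
#>  prs_L_MH   1359.9    1508.7         10.946   7.120 1.94e-05        TRUE
#>  prs_R_HA    914.4     621.7        -32.006 -11.127 2.52e-07        TRUE
#>  emg_L_GA     93.3      85.3         -8.547 -17.703 1.97e-09        TRUE
#>  emg_L_RF     96.9      97.0          0.115   0.421 6.82e-01       FALSE
```

Reading the rows: right-hallux peak pressure drops ~32% and the left
heel gains ~11% after the fatigue operator (both significant at
α = 0.05); the left gastrocnemius MDF falls 93.3 → 85.3 Hz
(significant), while the unfatigued rectus femoris does not move — the
qualitative pattern the pipeline is built to detect. The single-trial
MDF estimate (96 Hz) scatters around its analytic 93.6 Hz target with
1 Hz bin resolution.

## Command-line pipeline

```sh
Rscript inst/cli/gaitfatigue.R simulate config.json   # cohort CSVs + manifest
Rscript inst/cli/gaitfatigue.R analyze  config.json   # 16-row results CSV
Rscript inst/cli/gaitfatigue.R report   results.csv   # per-row text summary
```

`config.json` holds the synthetic-generator settings, analysis
parameters (filter band, spectrum estimator, step detection, alpha) and
paths; every random draw flows from its single `seed`, so reruns are
byte-identical.

## Package layout

| Module | Contents |
| --- | --- |
| `R/types.R`, `R/io.R` | signal/recording containers, CSV exchange, results I/O |
| `R/semg.R` | FIR bandpass, Welch/periodogram spectra, median frequency |
| `R/plantar.R` | step detection, per-region peak summaries, percent change |
| `R/stats.R` | paired t-test, per-channel comparisons, RPE summaries |
| `R/synthetic.R` | protocol config, sEMG/pressure generators, fatigue operator, cohorts |
| `R/pipeline.R` | cohort analysis, directory layout, simulate/analyze/report commands |

See `vignettes/fatigue-methods.Rmd` for the model assumptions, the
synthetic world's scope, and every numerical convention.
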