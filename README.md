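# breathsnr

Breathing-intensity analysis of bilateral lung sounds via the
signal-to-noise ratio.

Airflow obstruction (as in COPD) turns laminar airflow into turbulence and
weakens the breath sound heard at the chest wall. `breathsnr` quantifies
this from chest-wall (auscultation) audio with one metric: the SNR of the
recording, treated as a breathing-intensity score. Signal power is the
breath-band sound power during breathing activity; noise power is the
ambient background plus obstruction-induced turbulence, so more obstruction
means a lower SNR:

```
SNR_dB = 10 log10(P_S / P_N) = P_S,dB − P_N,dB
```

The received signal at each thorax sensor is modelled as the lung-sound
source convolved with a sparse multipath impulse response — a sum of
attenuated, delayed copies `Σ_j A_j x(t − τ_j)` per side — plus noise, and
the two sensors are combined by delay-and-sum with SNR-proportional weights.

The package is aimed at respiratory-acoustics researchers prototyping
wearable stethoscope pipelines. It provides, as pipeable tibble-returning
functions:

* **Synthesis** — an annotated simulator for single subjects and whole
  cohorts: breath-envelope sources, multipath channels with fabric
  attenuation, gated turbulence noise mapped from a 1–10 health-scale
  score, left-channel heart sounds, motion-artifact bursts, and
  ground-truth segments and SNR for every session
  (`simulate_cohort()`, `simulate_subject()`, `cohort_write()`).
* **Segmentation** — hysteresis breath-activity detection on an RMS
  envelope, exact two-means normal/deep classification, motion gating
  (`segment_session()`, `detect_activity()`, `motion_gate()`).
* **Spectral estimation** — Welch PSD normalized so density integrates to
  power, with exact band-power integration (`welch_psd()`, `band_power()`).
* **SNR** — quiet-interval noise estimation with ambient subtraction and
  the capped dB metric (`session_snr()`, `estimate_powers()`, `snr_db()`).
* **Bilateral array** — cross-correlation alignment, delay-and-sum
  combination with an incoherence fallback, array-gain reporting
  (`bilateral_snr()`, `estimate_delay()`, `combine_bilateral()`).
* **Cohort statistics** — per-subject dB aggregation, min-max normalized
  group means per health scale, Spearman correlation with a permutation
  p-value (`cohort_analysis()`, `correlation_test()`), with
  `tidy()`/`glance()`/`autoplot()` methods.

WAV (PCM16/float32) and motion/segment/metadata CSV readers and writers are
included, plus a thin CLI at `inst/scripts/breathsnr`
(`simulate`, `analyze`, `cohort` subcommands).

## Worked example

Simulate a healthy subject (health scale 8/10) performing 30 s of normal
then 30 s of deep breathing, and analyze both channels plus their bilateral
combination:

```r
library(breathsnr)

subj <- sim_subject("S001", health_scale = 8, group = "healthy", seed = 42)
sim  <- simulate_subject(subj, breath_program(
  depth_sequence = data.frame(depth = c("normal", "deep"),
                              duration = c(30, 30))
))
sim$recording
#> <recording> 2 channel(s) [left, right], 60.0 s @ 4000 Hz, with motion trace

bilateral_snr(sim$recording)[, c("channel", "snr_db", "n_active",
                                 "n_rejected", "array_gain_db",
                                 "peak_correlation")]
#> # A tibble: 3 × 6
#>   channel  snr_db n_active n_rejected array_gain_db peak_correlation
#>   <chr>     <dbl>    <int>      <int>         <dbl>            <dbl>
#> 1 left       23.7       11          2         NA              NA
#> 2 right      23.7       11          2         NA              NA
#> 3 combined   26.5       11          2          2.86            0.932
```

Each row is one analysis channel: ~23.7 dB of breathing SNR per sensor, 11
usable breath-active intervals, 2 intervals rejected by the motion gate,
and a combined-channel SNR 2.86 dB above the best single sensor (close to
the 3.01 dB two-element coherent limit), at an inter-channel peak
correlation of 0.93.

At cohort level, per-subject SNR is averaged in dB, group means per health
scale are min-max normalized, and the positive SNR–health association is
permutation-tested:

```r
coh <- simulate_cohort(
  n_healthy = 8, n_copd = 2, seed = 7,
  program = breath_program(depth_sequence = data.frame(
    depth = c("normal", "deep"), duration = c(15, 15))),
  rate = 2500
)
fit <- cohort_analysis(analyze_cohort(coh), n_permutations = 499, seed = 7)
glance(fit)
#> # A tibble: 1 × 4
#>     rho p_value     n n_permutations
#>   <dbl>   <dbl> <int>          <dbl>
#> 1 0.982   0.002    10            499
tidy(fit)
#> # A tibble: 6 × 4
#>   health_scale     n group_mean_snr_db normalized_snr
#>          <int> <int>             <dbl>          <dbl>
#> 1            4     2              12.7          0
#> 2            5     1              14.9          0.168
#> 3            6     1              17.5          0.363
#> 4            8     2              21.3          0.655
#> 5            9     3              24.0          0.856
#> 6           10     1              25.9          1
autoplot(fit)
```

Estimated SNR rises monotonically with the health scale (Spearman
rho = 0.98, one-sided permutation p = 0.002 over this 10-subject toy
cohort); the normalized column is the min-max scaled group-mean curve.

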