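---
title: "Breathing-intensity analysis from bilateral lung sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-intensity analysis from bilateral lung sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(breathsnr)
library(dplyr)
```

## The problem and the signal model

Airflow obstruction — the defining feature of chronic obstructive pulmonary
disease (COPD) — changes what a lung sounds like at the chest wall: an
obstructed airway carries less laminar airflow, and what flow remains is
turbulent. breathsnr quantifies this with a single acoustic metric, the
signal-to-noise ratio of chest-wall (auscultation) audio, treating the SNR as
a breathing-intensity score that falls as obstruction rises.

The received signal at each thorax sensor is modelled as the lung-sound
source convolved with a sparse multipath impulse response plus additive
noise,

$$ s_l(t) = \sum_{j=1}^{J} A_j\, l(t - \tau_j) + n(t), \qquad
   s_r(t) = \sum_{k=1}^{K} A_k\, r(t - \tau_k) + n(t), $$

where $l(t)$ and $r(t)$ are the left and right thorax sources, the
$(A_j, \tau_j)$ pairs are the attenuation factors and time delays of each
side's filter taps, and $n(t)$ is additive noise. The metric itself is

$$ \mathrm{SNR_{dB}} = 10 \log_{10}(P_S / P_N) = P_{S,\mathrm{dB}} - P_{N,\mathrm{dB}}, $$

with $P_S$ the breath-sound power during breathing activity and $P_N$ the
noise power: the sum of ambient background noise and the acoustic noise
generated by obstructed, turbulent airflow. Because obstruction feeds the
noise term (and starves the signal term), more obstruction means a lower
SNR.

Everything downstream follows from making those two power terms measurable:
segmentation decides *when* breathing activity happens, the spectral module
decides *how* power is measured, the bilateral array stage improves the
measurement with two sensors, and the cohort stage relates per-subject SNR
to a self-reported 1–10 health-scale score.

## How the powers are estimated

The model defines $P_N$ as ambient plus turbulence noise, but a recording
offers no way to observe turbulence separately from breath sound — both
happen exactly when air flows. The estimator therefore uses the only
observable proxy:

* $P_N$ = analysis-band power over the concatenated **quiet** intervals
  (ambient noise, measurable because turbulence needs airflow);
* $P_{raw}$ = band power over the concatenated **breath-active** intervals;
* $P_S = \max(P_{raw} - P_N,\ 10^{-6} P_N)$ — standard ambient subtraction
  with a floor so power can never go negative.

The consequence is documented rather than hidden: turbulence energy
co-occurring with airflow is attributed to $P_S$ to the extent it exceeds
the quiet-floor estimate. This preserves the metric's intent because of how
obstruction behaves physically: turbulent energy *replaces* clean
breath-sound energy rather than adding to it (an obstructed airway moves
less air overall). The synthetic severity map encodes exactly this — clean
breath-sound band power falls 2 dB per step of severity while turbulence
power rises 2 dB per step — and under it both the true and the estimated SNR
decrease monotonically with obstruction.

Reported SNR is capped at ±60 dB so noise-free and signal-free limits stay
finite and cohort averages are always defined. The capped identity
`snr_db = p_signal_db - p_noise_db` holds exactly in every result row.

All power terms are computed in a configurable analysis band, 100–1000 Hz
by default: breath sounds concentrate there, while DC drift sits below it
and most heart-sound energy (S1/S2 transients, roughly 20–150 Hz) falls
largely outside it. Spectra come from a Welch estimator (Hann window, 1 s
segments, 50% overlap) whose one-sided density is normalized so that its
integral over frequency returns total power; `band_power()` then integrates
by the trapezoid rule with interpolated band edges, making disjoint bands
add exactly and the full band satisfy Parseval against the time-domain
variance (within 2% for stationary 10 s inputs, tested).

## Segmentation and motion gating

Breath activity is detected on the band-passed signal's 100 ms / 25 ms RMS
envelope by hysteresis: enter active above 3.0x the noise floor, exit below
1.5x. The floor is the median of the lowest quartile of envelope frames — a
robust choice that survives sessions which are mostly breath-active, since
a field protocol never guarantees long silences. Active bursts
shorter than 250 ms are dropped and equally short quiet gaps merged (breath
bursts at rest last at least half a second). The resulting intervals always
tile the recording exactly.

Breath depth (normal vs deep) is classified per active interval by exact 1-D
two-means on the dB band powers — an exhaustive split search on the sorted
values, no random initialization — labelling the higher-power cluster
"deep". If the clusters separate by less than 3 dB everything is "normal":
absolute calibration across sensors and fabrics is unavailable, so depth is
meaningful only as a within-session contrast. Deep intervals are included in
$P_S$ by default; `include_deep = FALSE` restricts the estimate to normal
breaths for protocols that analyze the two depths separately.

A synchronized motion trace gates artifacts: any interval overlapping a
motion sample above 5x the trace baseline RMS is *flagged* motion-rejected
and excluded from power estimates. Gating never deletes samples — the
partition is untouched and the operation is idempotent.

## Bilateral combination

The two-sensor stage realizes the multipath match filters in their minimal
faithful form: single-tap delay-and-sum. The inter-sensor lag is the argmax
of the normalized cross-correlation within ±50 ms (chest acoustic paths
differ by far less), computed only over breath-active, non-rejected samples
— the coherent component is the breath signal, not the ambient noise. Ties
break toward the smallest |lag|, then negative. Channels are summed with
SNR-proportional weights normalized to 1; if the peak correlation is below
0.2 the channels are treated as incoherent and the combiner degrades to
selecting the better channel, so combination can never cost much against
the best single sensor. Estimating full multi-tap impulse responses from
data is deliberately out of scope.

Two closed-form limits anchor the tests: equal coherent signal with
independent equal-power noises must gain $10\log_{10} 2 \approx 3.01$ dB,
and fully correlated noise must gain nothing. Larger bilateral gains (~7 dB) reported for wearable
bilateral-stethoscope prototypes exceed the two-element coherent limit and
are treated as empirical, data-specific observations, not targets.

## The synthetic cohort

No public recordings exist for this task, so the package carries a
first-class simulator that every stage is tested against:

* **Source** — band-limited (100–1000 Hz) Gaussian noise modulated by a
  smooth breath envelope: one contiguous Tukey-shaped
  inspiration+expiration burst per cycle (12 breaths/min, 40% duty),
  expiration slightly quieter, deep blocks boosted 6 dB. The default
  program is four 60 s normal/deep blocks: a ~4 min session of
  normal-to-deep breathing transitions, the typical wearable pilot
  protocol.
* **Channel** — two taps per side (direct path plus a 0.4x reflection), the
  right direct path 0.75 ms later than the left; broadband fabric
  attenuation; white ambient noise (2e-3 W) everywhere; turbulence noise
  band-limited to the breath band (it is airflow-generated, so it is
  spectrally confounded with signal by design) and gated to breath-active
  intervals. Delays round to the nearest sample, making the convolution a
  sparse tap sum.
* **Heart sounds** — damped S1/S2 bursts at 72 bpm on the left channel
  only. Heart sounds are not breathing, yet they raise the
  measured left-thorax SNR in practice; whether their in-band power should
  count as signal is a genuine modelling choice, exposed as
  `heart_counts_as_signal` (default `TRUE`, reproducing the empirically
  higher left-channel SNR).
* **Severity map** — health scale $h \in 1..10$ maps to turbulence power
  $0.006 \cdot 10^{-(h-1)\cdot 2/10}$ W and clean band power
  $0.5 \cdot 10^{-(10-h)\cdot 2/10}$ W, i.e. 2 dB per step each way,
  spanning ~18 dB of turbulence and ~26 dB of true SNR across the scale.
  Ground-truth SNR uses the generator's own component bookkeeping (realized
  clean power over active samples; analytic in-band ambient plus exact
  turbulence power), so estimators are validated against known truth.
* **Cohort** — 35 healthy subjects with health scales skewed high (they are
  recruited at running events) and 3 COPD subjects with scales centered on
  5.5/10; ~70% male. Audio is materialized lazily per subject so large
  cohorts fit in memory, and everything is reproducible from one seed.
* **Motion artifacts** — 0–3 bursts per session, 0.3 s each, placed
  uniformly at random: a simultaneous broadband audio thump and a
  motion-trace spike at 8x the baseline RMS.

What the simulator does *not* emulate matters for interpreting green tests:
real adventitious sounds (crackles, wheezes) as clinical classes,
inter-subject anatomy, sensor coupling variation beyond a scalar fabric
loss, or real questionnaire noise in the health scale. Passing tests show
the pipeline recovers what the model generates; they are not clinical
validation.

## Cohort statistics

Per-subject SNR is the arithmetic mean in dB over channels and sessions
(normalized-SNR comparisons are dB-derived; watts-domain averaging would let
one loud session dominate). Results flagged low-confidence (fewer than 3
usable active or quiet intervals) are excluded unless nothing else remains.
Group means per occupied health scale are min-max normalized to [0, 1] —
the simplest reading of "normalized for comparison"; unoccupied scales are
omitted, never interpolated, and a fully degenerate (all-equal) profile is
an error by default. The association test is Spearman rank correlation
(health scale is ordinal) with a one-sided permutation p-value:
$p = (1 + \#\{\rho_{perm} \ge \rho_{obs}\})/(B+1)$, which is always in
$[1/(B+1), 1]$, reproducible under a fixed seed, and tie-safe via average
ranks. A constant SNR column raises an explicit undefined-correlation error
rather than silently returning 0. COPD subjects enter the pooled
correlation; the `group` column preserves the distinction for reporting.

## Numerical choices and degenerate inputs

* Band-pass filtering is frequency-domain and zero-phase with ideal edges,
  so filtered-component power bookkeeping is exact.
* Flat-zero envelopes segment to a single quiet interval (not an error);
  all-rejected segmentations raise an insufficient-data error naming the
  missing phase.
* The two-means depth split breaks ties toward minimal within-cluster
  variance (exhaustive search makes this deterministic).
* Noise-free simulation reports the +60 dB cap sentinel instead of
  infinity, and $P_S = 0$ reports the −60 dB floor.
* A threshold of 0 in the motion gate rejects every interval — the
  degenerate bound — and downstream estimation fails loudly.

## Problem sizes used in the test suite

The generator's defaults (4-min program, 35+3 cohort, 2 dB/step severity
map) are the study conditions; the automated tests run the same physics at
sizes chosen for a fast suite: 60 s sessions for the monotonicity,
segmentation-recovery and fabric sweeps (20 seeds, 4 severity levels),
2–4 min sessions for estimator consistency (median |error| ≤ 1 dB over a
0–30 dB truth range), 20 s two-channel fixtures for the array limits
(±0.5 dB), 5 s fixtures across 50 trials for ±1-sample delay recovery, and
40 s sessions at 2400 Hz for the 20-seed, 38-subject cohort power check
(500 table-level null cohorts calibrate the permutation test's type-I error
at 0.05 ± 0.02).

## A worked example

```{r example}
coh <- simulate_cohort(
  n_healthy = 8, n_copd = 2, seed = 7,
  program = breath_program(
    depth_sequence = data.frame(depth = c("normal", "deep"),
                                duration = c(15, 15))
  ),
  rate = 2500
)
results <- analyze_cohort(coh)
fit <- cohort_analysis(results, n_permutations = 499, seed = 7)
glance(fit)
tidy(fit)
```

```{r plot}
autoplot(fit)
```

## Known limitations

The quiet-interval noise estimator reads ambient noise only; its turbulence
bias is directional by design but means estimated SNR is not an unbiased
estimate of the model's true SNR for obstructed subjects. Depth labels are
within-session relative. The bilateral combiner assumes the lungs' sounds
are coherent across the chest — true by construction in the simulator's
shared-source mode, unverified on real subjects. Health-scale scores are
consumed as given; mapping them to clinical severity (spirometry, PFTs) is
future territory, not this package's claim.
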