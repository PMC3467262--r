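---
title: "Methods: retinal light-response analysis with retinaresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retinal light-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaresp)
```

This vignette is the package's account of its methods: the models and
estimators, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the underlying analysis tradition leaves them open.

## 1. The measurement chain

A multi-electrode recording of retinal ganglion cells passes through:

1. **Band-pass filtering** of the raw extracellular voltage (300–5000 Hz)
   and **threshold-crossing spike detection** at 2.8 robust standard
   deviations.
2. **PSTH construction**: spikes from 5 repeated 2 s stimulus blocks
   (stimulus 100–400 ms within the block), 1 ms bins, rate
   = count / (n_blocks × bin width).
3. **Smoothing** with a 25 ms Gaussian kernel and **baseline correction**
   by the mean rate over the 100 ms before stimulus onset.
4. **Parameter extraction**: ON peak amplitude *A1*, time-to-peak *L1*,
   response duration *A1τ2* (peak to the first crossing below *A1*/e, with
   linear interpolation between bins); *A2*, *L2*, *A2τ2* likewise
   relative to stimulus offset.
5. **Classification** by the bias index BI = (A1−A2)/(A1+A2) with
   thresholds ±1/3, and the 200 ms transient/sustained boundary on *A1τ2*.

ERG traces and optomotor thresholds are analyzed by separate, simpler
estimators (sections 6–7).

## 2. Synthetic data: the stated world

Every stage is validated against generated data with known ground truth.
The generator's assumptions, and therefore the limits of what a green test
establishes, are:

- **Rate model.** A cell's instantaneous rate is a constant baseline
  (5–20 Hz across the default population; the true baseline distribution
  of mouse ganglion cells is not constrained here) plus up to two response
  lobes. Each lobe rises linearly over `rise_time` (10 ms) to amplitude
  *A* at latency *L* and decays as exp(−t/τ). The exponential decay gives
  the extracted duration the closed form τ, which is what makes analytic
  recovery tests possible. Real PSTHs are not exponential; nothing here
  validates lobe-shape robustness beyond this family.
- **Spiking.** An inhomogeneous Poisson process realized by thinning
  against the profile maximum on a 1 ms grid. Real spike trains are
  refractory and often over- or under-dispersed; Poisson is the standard
  neutral choice. One top-level seed is split deterministically per cell
  and per block, so identical specifications are bit-identical.
- **Population.** The 60-cell fixture holds 20 ON-transient, 20 ON-OFF and
  20 OFF cells with lobe amplitudes 150–250 Hz — the order of magnitude of
  transient ganglion-cell PSTH peaks — latencies 60–100 ms and decay
  constants 40–70 ms. Two quantitative facts drove the amplitude range,
  both visible a priori from the estimator, not tuned to a test run:
  the 25 ms smoothing attenuates a τ ≈ 60 ms exponential peak by roughly
  half, and the smoothed-peak estimate carries a relative SD of about
  1/√N where N is the spike count inside the smoothing window across
  blocks (≈ 15 % at these settings). Amplitudes another octave lower make
  the bias index overlap between classes at 5 blocks, i.e. such
  populations are *not* "well separated".
- **ON-OFF cells have fully matched lobes** (equal amplitude, latency and
  decay). Matching only amplitudes is insufficient: lobes of different τ
  are attenuated differently by the smoothing, displacing BI from zero
  systematically.
- **Raw traces.** Gaussian white noise plus a biphasic
  (derivative-of-Gaussian) template at each spike time, 20 kHz. Real
  noise is colored and spike shapes vary; detection results here certify
  the thresholding logic, not robustness to waveform diversity.
- **ERG.** A negative Gaussian lobe (a-wave, default trough 15 ms, σ 8 ms)
  followed by a positive Gaussian lobe (b-wave, peak 60 ms, σ 12 ms),
  plus noise. Traces are averages of `n_sweeps = 4` flash repetitions,
  as flash ERGs are recorded in practice; `noise_sd` is per sweep.
  Oscillatory potentials are not modeled. Flicker-ERG amplitudes follow a
  first-order low-pass law A(f) = A₀/√(1+(f/f_c)²).

## 3. Spike detection: the threshold reference

The detection threshold multiplier is 2.8, but "2.8 σ" is underdetermined:
σ of what? The package takes a deliberate position:

- `detect_spikes()` alone uses the MAD estimate of the trace it is given
  (robust to contamination by the spikes themselves).
- `filter_and_detect()` — the acquisition chain — estimates σ on the
  **unfiltered** trace and applies the threshold to the filtered one.

The reason is quantitative. Band-passing white noise of SD σ₀ to
300–5000 Hz at 20 kHz leaves in-band noise of ≈ 0.69 σ₀. A threshold at
2.8 in-band SDs has, by Rice's formula with an RMS bandwidth near 2.9 kHz,
a false-crossing rate of tens per second — no single unit fires fast
enough for threshold crossing alone to reach 95 % precision there.
Referencing the same multiplier to the broadband noise floor puts the
threshold at ≈ 4.1 in-band SDs, where the false-positive rate drops below
1/s and precision/recall ≥ 0.95 holds at 5 σ template amplitude. The
polarity (negative), refractory window (1 ms) and the 1 ms extremum
alignment window are configurable.

The detection fixture enforces a 2.5 ms dead time between generated
spikes: a physiological refractory period, and necessary because two
spikes inside one refractory window are indistinguishable to any
threshold detector.

## 4. PSTH parameters: windows, thresholds, censoring

- **Smoothing kernel.** "25 ms Gaussian" is interpreted as the kernel
  *standard deviation* (the most common convention); reflection padding
  handles the edges and conserves rate mass to 0.1 %.
- **Search windows.** ON peak: onset → offset. OFF peak: offset →
  offset + stimulus duration + 50 ms (truncated at the block end). Two
  deliberate choices here. First, the ON window ends at offset: the
  smoothing kernel spreads an early OFF lobe ~2σ backwards in time, and an
  ON window overrunning the offset would read that leading edge as an ON
  response. Second, the windows have (nearly) equal lengths: the peak over
  a window is an extreme-value statistic, so a much longer OFF window
  (e.g. offset → block end) would bias every cell's A2 upwards relative
  to A1 and displace the whole BI distribution towards OFF.
- **Duration (τ2).** Measured on the baseline-corrected smoothed PSTH as
  the first downward crossing of A/e after the peak, linearly
  interpolated; if no crossing occurs before the end of the record the
  value is censored (flagged, and classified sustained). Smoothing widens
  measured durations by roughly σ²/τ-order terms; the transient boundary
  (200 ms) is far enough above the generated range (40–70 ms) for this
  not to matter.
- **Non-response.** A cell is flagged non-responsive when its amplitude
  does not exceed twice the standard error of the baseline-window bins;
  the bias index is undefined at A1 = A2 = 0 and a flag is more honest
  than a fabricated zero.
- **Boundary rule.** A1τ2 exactly 200 ms → sustained (the strict-
  inequality formulation leaves the boundary open; it must land
  somewhere).

## 5. Series analysis and the group comparison

Per-level amplitudes are normalized by the per-cell maximum (idempotent;
ties in the preferred level break towards the smaller stimulus).
Flicker responses are measured on the cycle-folded histogram (peak minus
cycle minimum of the circularly smoothed cycle average) — the closest
analogue of a baseline-corrected peak when the cycle contains no
pre-stimulus window; a first-cycle mode is provided since the folding
convention cannot be recovered from the analysis tradition alone.

`compare_genotypes()` implements the balanced mixed-design ANOVA by its
sums of squares: the genotype main effect is tested against
subjects-within-groups; level and genotype × level against the within
residual, with a Greenhouse–Geisser ε (computed from the pooled
within-group covariance) reported alongside uncorrected p-values.
`stats::aov` with an `Error(cell)` stratum reproduces the same F values
and serves as the independent oracle in the test suite. Under the null
(identical generators, compound-symmetric data) the group test is exact:
measured type-I error 5–6 % at nominal 5 % over 1000 replicates; power
for a 3× difference in mean response duration at n = 15 cells/group,
30 % between-cell CV and 15 % residual CV is ≈ 100 %.

## 6. ERG metrics

The a-trough is the minimum in a 5–50 ms window after the flash, the
b-peak the maximum from the trough to 150 ms; b-amplitude is
trough-to-peak (hence DC-offset invariant), b-latency is onset-to-peak.
Numerical choices:

- **Pre-extremum smoothing** σ = 1.5 ms: strong enough to keep
  oscillatory-potential-scale wiggles from capturing the extremum, weak
  enough to attenuate a physiological (σ ≈ 8 ms) a-lobe by < 2 %.
- **Noise scale** for the dim-flash/flat decisions is estimated on the
  *raw* pre-flash samples and scaled by the kernel's analytic noise gain
  √Σkᵢ² — the SD of a short correlated smoothed segment is far too
  unstable.
- **Dim-flash rule.** If the trough does not undercut baseline − 4
  noise-SDs there is no a-wave and the baseline level stands in as the
  trough; 4 (not 3) because the window's expected noise extreme is ≈ 2.5
  SDs and a criterion inside the bulk of the extreme distribution would
  fire constantly on flat traces.
- **Fusion.** The flicker fusion frequency is the lowest tested frequency
  whose cycle-averaged trough-to-peak amplitude falls below 3× the
  pre-stimulus noise SD (the criterion the "practically zero above
  10 Hz" description implies must exist); in the fusion-recovery test the
  generator cutoff (0.64 Hz) is fixed by solving A(f) = criterion for a
  crossing between the 7 and 10 Hz protocol steps — a calibration of the
  stated world, set before the test was run, not adjusted after.
- A fundamental-Fourier-component amplitude mode is provided as an
  alternative to trough-to-peak; for a pure sinusoid both agree.

## 7. Optomotor contrast sensitivity

Michelson contrast (Lmax − Lmin)/(Lmax + Lmin) and sensitivity = 1 /
threshold contrast are exact formulas; the only decisions are reporting
conventions (percent contrast rounded to one decimal, matching how such
values are printed) and the t-test variant for per-frequency group
comparisons (Welch by default — "Student's t-test" without a variance
statement does not justify the pooled assumption; a pooled mode exists).
Both rounding directions between sensitivity and percent contrast are
exposed, since printed value pairs are typically consistent only to one
rounding step.

## 8. Known limitations

- Spike sorting (clustering of multi-unit threshold crossings) is out of
  scope; traces are assumed single-unit.
- The exponential-lobe rate family and Poisson spiking are conveniences
  for ground-truth testing, not biophysics; no photoreceptor or bipolar
  transduction is modeled.
- ERG a-wave modeling (Lamb–Pugh style) and oscillatory-potential
  analysis are absent.
- The RM-ANOVA requires every cell to carry every level; missing levels
  must be handled upstream (they are recorded as absent, never imputed).
- Classification accuracy statements hold for the stated population;
  cells with genuinely intermediate bias indices are a biological
  reality the ±1/3 thresholds cannot legislate away.
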