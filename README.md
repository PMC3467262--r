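# retinaresp

Quantitative analysis of retinal light responses for electrophysiologists:
extracellular spike detection, peri-stimulus time histogram (PSTH)
parameterization and ganglion-cell classification, stimulus-series
statistics, electroretinogram (ERG) a-/b-wave metrics with flicker-fusion
estimation, and optomotor contrast-sensitivity computation. A synthetic-data
generator with known ground truth makes every stage testable without
recordings.

## The analysis in brief

**Spike detection.** Raw 20 kHz traces are zero-phase band-pass filtered
(300–5000 Hz) and spikes detected by negative threshold crossing at
*k*·σ (default *k* = 2.8), with σ estimated robustly (MAD) and events
aligned to the waveform extremum.

**PSTH parameters.** Spikes from 5 repeated 2 s stimulus blocks (300 ms
spot, 100 ms pre-onset delay) are binned at 1 ms, smoothed with a 25 ms
Gaussian, and corrected by the mean rate over the 100 ms before onset.
From the corrected PSTH the package extracts, for the ON response:

- *A1* — peak rate after stimulus onset (Hz, baseline-corrected),
- *L1* — time from onset to the peak (ms),
- *A1τ2* — response duration: time from the peak to the first crossing
  below *A1*/e (ms),

and analogously *A2*, *L2*, *A2τ2* relative to stimulus offset.

**Classification.** The bias index

> BI = (A1 − A2) / (A1 + A2) ∈ [−1, 1]

separates ON (BI → +1), OFF (BI → −1) and ON-OFF (BI ≈ 0) ganglion cells;
ON cells with *A1τ2* < 200 ms are transient, otherwise sustained.

**Series statistics.** Metrics across spot-size (75–1700 µm), intensity
(−4 to 2 log cd·s/m²) and flicker (1–15 Hz) series are normalized per cell
and genotype groups compared by repeated-measures two-way ANOVA
(group × stimulus level, Greenhouse–Geisser corrected within-effects).

**ERG.** The b-wave amplitude is measured from the a-wave trough to the
following b-wave peak, the b-wave latency from flash onset to that peak.
Flicker series (0.5–30 Hz) yield cycle-averaged amplitudes and the fusion
frequency (first amplitude below 3× the pre-stimulus noise SD).

**Optomotor.** Michelson contrast (Lmax − Lmin)/(Lmax + Lmin); contrast
sensitivity is the reciprocal threshold contrast, summarized per spatial
frequency.

## Worked example

```r
library(retinaresp)

epoch <- stimulus_epoch()                  # 2 s block, stimulus 0.1-0.4 s
spec  <- cell_spec("ON-transient",
                   rate_profile(10, on_amp = 200, on_latency = 80,
                                on_tau = 60),
                   n_blocks = 5, seed = 42)
train <- simulate_spike_train(spec, epoch)
train
#> <spike_train> 5 block(s) x 2.0 s, 166 spikes total

m <- response_metrics(train, epoch)
round(c(baseline = m$baseline, A1 = m$A1, L1 = m$L1, A1tau2 = m$A1tau2), 1)
#> baseline       A1       L1   A1tau2
#>     11.8     96.2    100.0     85.4

bi <- bias_index(m$A1, m$A2)               # 0.954 -> pure ON
classify_polarity(bi)                      #> "ON"
classify_kinetics(m$A1tau2)                #> "transient"  (85 ms < 200 ms)
```

The extracted amplitude (96 Hz) is the 25 ms-smoothed peak of a 200 Hz
exponential lobe — smoothing halves sharp transients, which is why
classification compares smoothed amplitudes against each other, never
against the generator amplitude. The recovered duration (85 ms) sits near
the generating decay constant (60 ms) plus the widening contributed by the
smoothing kernel.

ERG and behaviour:

```r
erg <- measure_single_flash(
  simulate_erg(erg_spec(a_amp = 100, b_amp = 300, noise_sd = 15), seed = 1))
round(c(a = erg$a_amplitude, b = erg$b_amplitude, lat = erg$b_latency), 1)
#>     a     b   lat
#> 104.2 404.4  60.0      # trough-to-peak b-wave = a_amp + b_amp

contrast_sensitivity(0.119)   #> 8.4  (threshold contrast 11.9%)
contrast_percent(8.4)         #> 11.9
```

## Pipeline / CLI

```sh
Rscript inst/cli/retinaresp all --seed 1 --out results/
```

Stages: `simulate | detect | psth | classify | series | erg | optomotor |
all`. Outputs are delimited text plus a JSON report; identical config and
seed give byte-identical tables.

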