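# voltscope

Analysis toolkit for two-photon **genetically encoded voltage indicator
(GEVI)** recordings — fluorescence traces and movies whose brightness
tracks membrane potential. It covers the full chain from raw data to
biology: preprocessing (background, motion, pixel selection, photobleach
correction, ΔF/F₀ baselines), high-throughput screening metrics, indicator
biophysics (kinetics and voltage-response fits), optical spike inference,
ground-truth evaluation against electrophysiology, stimulus-locked
functional mapping, and freely-moving spatial analysis. A synthetic-data
module generates every input with exact ground truth, so each stage is
verifiable without external data.

It is written for labs doing voltage imaging at imaging rates from
~100 Hz (resonant scanning) to >7 kHz (random-access photon counting),
and for indicator engineers screening sensor variants.

## The models and statistics at the core

**Forward model (synthetic data).** Membrane potential `V(t)` (voltage
steps, evoked spike trains, bursts riding on up states, or Poisson
spiking on Ornstein–Uhlenbeck subthreshold noise) drives steady-state
fluorescence through a logistic sigmoid

    F(V) = L / (1 + exp(-k (V - x0))) + b,        ΔF/F0 vs mV,

anchored so F(−70 mV) = 0 and passing through ΔF/F₀ = 0.874 at −40 mV and
2.27 at 0 mV. Fluorescence relaxes toward F(V(t)) by exact exponential
update with direction-dependent multi-exponential kinetics (on: 2.8 ms;
off: 2.4 and 9.1 ms at equal weight by default). Photon counts per
imaging frame are Poisson with mean `flux · Δt · (1 + ΔF/F) · bleach(t)`.

**Spike inference.** Three detectors:

* *Adaptive KDE threshold*: after 20-Hz high-pass filtering and
  first-pass peak detection, the threshold maximizes
  `g(x) = Fmax(x)^p − Fnoise(x)^p` over an amplitude grid, where `Fmax`
  is the tail integral of the Gaussian KDE of peak amplitudes and
  `Fnoise` the tail of the KDE reflected about the median (`p = 0.1`).
* *Delayed-differential detector* (kHz photon-count traces): a 2-ms
  signal mean minus a delayed 3-ms baseline mean, sharpened by the
  positive >250 Hz content of that differential, z-scored; events exceed
  20 SD.
* *Sliding-SD detector*: peaks above 3.5× the sliding standard deviation
  of a 15-Hz high-passed ΔF/F trace, with false positives calibrated by
  re-running on the sign-inverted trace.

**Evaluation.** Electrophysiological spike times map to the nearest frame
center; a true positive is a truth spike with an optical event in the
same or next two frames (greedy one-to-one matching, burst regions
excluded); precision/recall/F1 curves are swept over threshold scales
0.1–2.2 and pooled across recordings by summing counts.

**Downstream readouts.** Pixelwise orientation maps by projecting
per-direction regression coefficients onto `exp(2iθ)/sqrt(N/2)`;
modulator-phase binning of 2–10 Hz Hilbert amplitude into 65 phase bins;
occupancy-normalized rate maps (2.5-cm bins, 3-cm Gaussian smoothing) and
a border score `(c − d̄)/(c + d̄)` validated by a 200-fold circular-shift
shuffle.

## Worked example

Simulate 30 s of an in-vivo-like single-neuron photon-counting recording
(1-ms APs at ~1 Hz on subthreshold noise, 2.9-ms effective off-kinetics,
spike SNR ≈ 8), detect spikes, and score against the known ground truth:

```r
library(voltscope)

v <- simulate_voltage("spontaneous", duration_s = 30, sim_rate = 14200,
                      seed = 42, rate_hz = 1, ou_sigma_mV = 2,
                      amplitude_mV = 75, fwhm_ms = 1)
model  <- gevi_model(tau_off_ms = data.frame(tau_ms = 2.9, weight = 1),
                     flux = 7.8e5)
dff    <- voltage_to_dff(v, model)
counts <- emit_photons(dff, model, frame_rate = 7100, seed = 43)
counts
#> <vs_trace> 212999 samples @ 7100 Hz (30.000 s), units=photons

spikes <- detect_ulove(counts)
spikes
#> <vs_spikes> 29 events (ulove detector)

m  <- match_spikes(v$spike_times_s, spikes, 7100, window_frames = 25,
                   burst_isi_ms = NULL)
pr <- precision_recall(m)
sprintf("precision %.3f, recall %.3f, F1 %.3f",
        pr$precision, pr$recall, pr$f1)
#> "precision 1.000, recall 0.967, F1 0.983"

spike_snr(counts, spikes, method = "shot_noise")$mean
#> 6.24

sta <- spike_triggered_average(
  vs_trace(counts$values / mean(counts$values) - 1, 7100, "dff"),
  spikes, window_s = c(0.02, 0.04), baseline_rule = "pre500ms")
spike_metrics(sta$sta)[c("amplitude", "fwhm_ms", "tau_off_ms")]
#> amplitude 0.70 dF/F, FWHM 2.81 ms, tau_off 3.14 ms
```

The detector recovers 29 of 30 true spikes with no false positives; the
averaged optical spike has the ~0.7 ΔF/F₀ amplitude, ~2.8-ms width and
~3-ms repolarization that the forward model injects.

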