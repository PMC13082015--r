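---
title: "Models and methods for voltage-imaging analysis with voltscope"
author: "voltscope authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods for voltage-imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voltscope analyzes fluorescence recordings of genetically encoded voltage
indicators (GEVIs): sensors whose brightness tracks membrane potential,
imaged under two-photon microscopy at rates from ~100 Hz to above 7 kHz.
This vignette explains the models the package implements, the
conventions behind each analysis, the synthetic-data generator that makes
everything testable, and the design decisions taken where the underlying
methods are under-specified.

# The forward model

## Voltage

`simulate_voltage()` produces four protocols. *Steps* reproduces a
voltage-clamp command series: 4 s at the −70 mV holding potential, then
1-s steps to 90, 70, 50, 30, 20, 0, −20, −40, −60, −80, −100 and −120 mV,
each separated by 1 s back at hold. *Spike trains* superimpose
action-potential waveforms with configurable amplitude and width — the
template is a Gaussian with exact FWHM; APs repolarize quickly, and a
heavy-tailed template would let the residual voltage tail, amplified by
the steep sigmoid just above rest, dominate the optical spike width.
*Burst-on-up-state* places spikes on a sustained ~24-mV subthreshold
plateau. *Spontaneous* draws spike times from a Poisson process with a
refractory minimum gap and adds Ornstein–Uhlenbeck subthreshold
fluctuation (time constant 50 ms). The OU parameters are placeholders:
in-vivo subthreshold spectral content is not standardized, so the default
SD is a configurable fixture, not a claim about cortex.

## Fluorescence

The steady-state fluorescence-voltage relation is the logistic sigmoid
`F(V) = L/(1 + exp(-k (V - x0))) + b` in ΔF/F₀ units. The default
parameters are solved once, deterministically, so that the curve anchored
to 0 at −70 mV passes through 0.874 at −40 mV and 2.27 at 0 mV (with the
inflection fixed at −25 mV, a one-parameter choice inside the anchored
family); this gives L ≈ 4.66, k ≈ 0.031/mV and a resting-gain of
~0.023 ΔF/F₀ per mV.

Kinetic relaxation toward the sigmoid target uses the *exact* exponential
update per simulation step (`F ← S + (F − S)·exp(−Δt/τ)`), not an Euler
step, so the single-component limit matches the analytic RC solution to
1e-6 and tests can assert it. Direction is chosen by the sign of
(target − current fluorescence): on-kinetics when brightening (default
2.8 ms), off-kinetics when dimming (default 2.4 and 9.1 ms at equal
weight). Multi-component states evolve independently with fixed weights;
at a direction switch the newly active components are re-initialized at
the current total. A consequence worth knowing: for brief APs this
equal-weight rule lets the slow off-component carry half of the decay,
producing optical spikes of ~5–6 ms width, wider than the 2.6 ± 0.5 ms
observed in vivo for this indicator class. The in-vivo emulation fixtures
therefore use the *measured in-vivo effective repolarization* — a single
2.9-ms off component — together with 1-ms-FWHM APs (cortical neurons at
body temperature; the 2-ms waveform is a room-temperature in vitro
protocol). With those settings the generator reproduces the in-vivo
triplet: spike amplitude ~0.7–0.9 ΔF/F₀, FWHM ~2.6–3.0 ms, fitted
repolarization ~3 ms.

## Photons and movies

`emit_photons()` integrates ΔF/F over imaging frames (samples are
assigned to frames by timestamp, so the output timebase is exact for any
rate ratio) and draws Poisson counts with mean
`flux · Δt · (1 + ΔF/F) · bleach(t)`; the bleach envelope is a
multi-exponential normalized to 1 at t = 0. Shot noise is the only
detector noise modelled — no read noise, no PSF, no scattering.
`render_movie()` paints disc-shaped cells plus uniform neuropil, applies
per-frame integer translations, and draws per-pixel Poisson noise;
injected shifts, masks and per-cell ΔF/F are returned as ground truth.
`simulate_population()` builds three study designs: interleaved
drifting-grating trials driving von Mises-tuned units (0.5-s blank +
0.5-s stimulus), a slow 0.1–1 Hz modulator whose phase gates 2–10 Hz
voltage-band amplitude at an injected lag, and open-field exploration of
an 80 × 80 cm arena by a reflected-OU trajectory with a border- or
center-tuned Poisson unit.

What the generator does *not* emulate: optical blur, depth attenuation,
non-rigid deformation, correlated network activity, electrode artifacts.
Tests passing on these fixtures demonstrate algorithmic correctness, not
robustness to every property of real tissue.

# Preprocessing conventions

*Background* is the mode of the first frame's intensity histogram, unit
bins for integer data and Freedman–Diaconis bins otherwise, excluding
pixels saturated at any point of the movie.

*Motion correction* is two-step rigid: integer shifts by FFT phase
correlation against the global average template, then subpixel refinement
(3×3 centroid of the correlation peak) against a local rolling template
(3–30 s). Because the first template is blurred by the motion itself, the
integer stage runs twice, the second pass against the sharpened
post-correction template. Shifts are estimable only up to a common
reference (the template's own displacement), so the table is re-centered
on its median; recordings whose mean shift exceeds 10 µm are flagged for
exclusion.

*Pixel selection* ranks foreground pixels by Pearson correlation with the
mask-mean template and keeps the ranking prefix whose summed trace
maximizes SNR. The screening SNR is defined here as (peak of the summed
trace − baseline mean)/(baseline SD) with the first 100 ms as baseline —
the underlying method leaves this undefined, so it is an explicit,
configurable decision. Selections under 300 pixels reject the field of
view.

*Photobleach fitting* tries 1–3 exponential components plus offset
(Levenberg–Marquardt, log-linear tail initialization, retried over spread
tau starts because coincident starting time constants make the Jacobian
singular). The reported model is the best R² (ties by RMSE, then MAE)
among orders at which both BIC and AIC are at a local minimum across
orders — the anti-overfitting guard. Correction divides by the fit
normalized to 1 at t = 0. The late bleaching phase (after 60 s) is
summarized by the slope of log10 F vs log10 t after 1-Hz low-pass
filtering and 140× downsampling.

*ΔF/F₀ baselines*: rolling bottom-5th-percentile over 30-s windows
(evaluated on a coarse step and interpolated), a fixed-window mean, the
0.3–0.5-s span of each stimulation cycle's blank period, or
subtract-and-divide by a 0.1-Hz low-pass trend. Constant traces map to
exactly zero under every method.

All zero-phase filtering de-means the signal first and pads the edges by
odd-symmetric reflection before forward–backward Butterworth filtering;
plain `filtfilt` starts from zero state and otherwise produces large edge
transients on offset-carrying traces.

# Screening metrics

Per field of view: relative brightness `B` (mean of the first 20 frames,
indicator channel over reference channel), response amplitude
`R = max(F/F0) − 1 − SD(Fpre/F0)` (F0 from the first 100 ms, Fpre the
100 ms before the pulse), photostability `P` (trapezoid area under the
normalized bleaching trace divided by the ideal non-bleaching area), and
the compound indices `DI = R·B^e`, `DB = R·(B·P)^e`. The brightness
exponent defaults to ½ — the shot-noise-limited reading, where a response
competes with noise growing as the square root of the collected flux —
with the linear convention available, since the printed formulas are
typographically ambiguous. Wells aggregate field-of-view records by
pixel-count weight.

# Spike detection

Three detectors cover the acquisition regimes.

**Adaptive KDE threshold** (imaging-rate traces). High-pass at 20 Hz
(causal), strict local maxima with 2-sample separation, then a Gaussian
KDE of peak amplitudes (Scott's-rule bandwidth). The noise distribution
is the KDE reflected about the median amplitude (symmetric-noise
assumption). On a 512-point amplitude grid the threshold maximizes
`g(x) = Fmax(x)^p − Fnoise(x)^p` with stringency p = 0.1; tail integrals
are computed exactly as mixtures of normal upper tails, and argmax ties
resolve to the smallest amplitude. A multiplicative scale on the
threshold supports precision-recall sweeps.

**Delayed-differential detector** (kHz photon counting). High-pass at
40 Hz, then the contrast trace: mean over 2 ms ("signal") minus the mean
over 3 ms delayed by 1 ms ("baseline", placed so it avoids the rising
phase), multiplied by the positive >250-Hz content of that differential,
and z-scored; samples above 20 SD, merged within 1 ms, are events. Event
onsets are the local peak of the 3-ms rolling regression slope on a
10-kHz interpolated copy. One deliberate choice: both filters run
zero-phase. A causal 2nd-order 40-Hz filter attenuates the ~3-ms optical
spike by about a third, and with the fixed 20-SD rule that costs most
true events at realistic SNR; zero-phase filtering preserves amplitude
and timing and is standard for offline analysis. The 1-ms merge window is
the detector's only dead-time parameter.

**Sliding-SD detector** (frame-rate ΔF/F). 3rd-order 15-Hz high-pass
detrending, events above 3.5× the sliding standard deviation (1-s window
by default). Re-running the identical analysis on the sign-inverted trace
estimates the false-positive rate as the inverted/upright count ratio;
note that causal detrending rings after large spikes, so the inverted
count is conservative (biased high) on strongly spiking cells.

Post-processing: bilateral singlet isolation (50 or 100 ms by context),
spike-triggered averages with two per-event baseline rules (the 20 frames
ending 5 frames before the peak, computed on a spike-interpolated copy of
the trace; or the snippet's own −500…0 ms mean), SNR under three noise
conventions (pre-peak −75…−25 ms SD; shot noise `1/sqrt(mean count)`; a
dynamic spike-free estimate — twice the SD of downward deviations from a
±1-s local mean over a ±5-s window, which for Gaussian noise of SD σ
equals `2σ·sqrt(1/2 − 1/2π)`), the shot-noise discriminability
`d' = ΔF/F · sqrt(photons in the FWHM window)` (the literature formula is
not printed in full anywhere accessible, so this definition is the
package's own, stated as such), rolling spike rate (1-min window, 250-ms
steps, normalized to the first minute), and subthreshold fluctuation
(0.1–50 Hz band, speed < 1 cm/s mask, 1st percentile low state vs
median-at-onset high state). The high state samples spike onsets, so a
smeared spike transient leaks into it through the 50-Hz edge of the band;
the magnitude is therefore a slight overestimate of the pure subthreshold
component on strongly spiking cells.

# Evaluation against electrophysiology

Truth spike times are mapped to the nearest imaging frame center
(sample i covers [(i−1)/r, i/r), stamped at (i−0.5)/r everywhere in the
package). A true positive is a truth spike with an unmatched optical
event in the same or the next two frames; matching is greedy
earliest-first and one-to-one, which on these interval structures attains
the maximum bipartite matching (asserted against an augmenting-path
oracle in the tests). Truth spikes closer than 100 ms mark burst regions
excluded from both sides of the evaluation; the cutoff is configurable
since the underlying criterion is unstated. Zero-division conventions:
precision 1 with no detections, recall 0 when truth exists but nothing
was found (NA for empty truth), F1 = 0 when both vanish. Threshold
curves sweep scales 0.1–2.2; pooling sums TP/FP/FN across recordings
per scale before recomputing the metrics, and the population-uniform
scale maximizes the pooled F1.

Subthreshold correspondence low-passes both traces at 50 Hz, interpolates
fluorescence to the electrophysiology rate, forms a 150 × 150 joint
probability histogram and reports the linear-regression slope in ΔF/F₀
per mV. On generator data this recovers the analytic sigmoid slope at
rest within a few percent.

# Functional mapping

Direction regressors evaluate
`R(t) = (1 − e^{−max(0, t−t_on)/τ}) − (1 − e^{−max(0, t−t_off)/τ})` with
τ = 0.7 s at frame centers. Pixel time series are detrended
(subtract-and-divide by a 0.1-Hz low-pass), centered, and scaled by their
root-sum-of-squares; coefficients come from ordinary least squares, which
reduces to the plain projection when the design is orthogonal and stays
correct when it is not. The complex projection `Σ c_j e^{2iθ_j}/√(N/2)`
yields orientation (phase, mod π) and tuning strength (magnitude); a
direction-symmetric response cancels exactly. Visual responsiveness uses
per-direction one-tailed Welch t-tests of stimulation-window versus
blank-window trial means at the Bonferroni-corrected level 0.05/8 (the
variance assumption is unstated in the source convention; Welch is the
safer default). The multimodal analysis band-passes voltage 2–10 Hz
(zero-phase Hamming FIR, order three times the longest period in band),
takes the Hilbert amplitude, band-passes it 0.1–1 Hz, bins it by the
0.1–1 Hz modulator phase into 65 bins with a circular 3-bin smooth, and
cross-correlates 0.1–2 Hz filtered, z-scored trace pairs with the peak
lag constrained to ±3 s. Pupil-based quiet-wakefulness epochs require a
dilation longer than 1 s and constriction faster than 0.2 mm/s, tolerate
under 25% missing samples, and exclude anything within 3 s of running
(speed > 1 cm/s sustained 1 s); every rejected epoch carries a reason
code.

# Spatial analysis

Speed comes from consecutive tracked positions (likelihood > 0.7, gaps
linearly interpolated, 0.5-s smoothing); head direction is the
left-to-right ear vector rotated 90° counterclockwise. Rate maps divide
spike counts by occupancy on 2.5-cm bins visited at least 0.1 s, with
samples below 2.5 cm/s removed, then smooth with a masked, renormalized
3-cm Gaussian. Firing fields are 4-connected components (connectivity is
a stated choice) of the smoothed map above 30% of the session peak with
at least nine bins; the smoothed map is used for the threshold because it
is what the field displays. The border score compares the best wall
coverage c (fraction of visited wall-edge bins belonging to a field)
with the rate-weighted mean field distance to the nearest wall d̄,
normalized by half the arena extent: `(c − d̄)/(c + d̄)`, −1 for central
fields, +1 for wall-hugging fields. Significance comes from circularly
shifting the spike sequence along the trajectory by Uniform(30 s,
duration − 30 s), 200 times; a cell is border-tuned if the observed score
beats the 95th null percentile *and* exceeds 0.5.

# Numerical choices and degenerate inputs

Multi-exponential fits (bleach, step kinetics) use Levenberg–Marquardt
with log-linear tail initialization restricted to the early decay (the
noise floor otherwise flattens the slope), multi-start over tau spreads
with the best residual sum of squares kept, and — for step kinetics — the
onset constrained to ±3 ms around its smoothed-derivative estimate, since
a free onset lets the fast component absorb onset error into a spurious
time constant. Components slower than 0.25 s are flagged as
photobleaching and excluded from the kinetic fractions. Residuals are
unweighted. Constant traces short-circuit to exact degenerate answers
(zero ΔF/F, offset-only fits, identity corrections). The downsampling
analysis linearly upsamples to 1 MHz and samples at 20 phase offsets per
output period; at the native rate the peak CV is zero only to
interpolation precision (~1e-4 on a ~3-ms spike), exactly zero for pulses
wider than the sampling interval.

Fixture scales used by the test-suite and the acceptance script — chosen
as the smallest sizes at which the statistical assertions are stable:
60-s kHz-rate recordings at ~1 Hz firing for detector evaluation; 100
seeded kinetics fits on 1.2-s traces (noise drawn at the 80-kHz
acquisition rate, SNR 20 per acquisition sample, block-averaged 4× to
20 kHz — the acquisition-faithful reading of the kinetics protocol);
32 × 32-pixel, 8-direction × 10-trial tuning movies; 10-min open-field
sessions with 200-shuffle nulls over 20 seeds.

# Known limitations

Rigid translation only (no rotation or non-rigid warp); cell
segmentation is an input, never computed; the kinetic state model is
phenomenological (independent weighted exponentials, not a Markov
photocycle), which over-widens brief optical spikes under multi-component
off-kinetics; shot noise is the only noise source in the generator; the
dynamic spike-free noise estimate and the inverted-trace false-positive
calibration both interact with causal filter ringing on strongly spiking
cells; and the subthreshold high state carries a small spike-leak bias by
construction.
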