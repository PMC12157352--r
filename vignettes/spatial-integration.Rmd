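---
title: "Linearity of spatial summation across cortical layers: model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linearity of spatial summation across cortical layers: model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Neurons in primary visual cortex integrate visual input from a region of
space far larger than their classical, spiking receptive field.  When a
drifting grating is confined to disks of increasing diameter, the response
grows to a peak and is then suppressed; yet an annulus ("ring") confined
entirely to the suppressive region can still depolarise some cells strongly.
How linearly a neuron sums input from complementary regions of space —
and how that linearity differs between cortical layers — constrains the
circuit that builds the receptive field.

`v1rings` implements a two-layer conductance-based spiking model of cat V1
(an LGN front-end feeding layer 4, which feeds layer 2/3 with long-range
orientation-biased horizontal connectivity), the disks-and-rings
stimulation protocol, and the analysis chain that turns membrane-potential
and spike recordings into four spatial-integration indices:

* **Suppression index** `SI = 100 (Dpeak - Dlargest) / Dpeak` — percent
  response loss from the best disk to the largest disk (baseline
  subtracted).
* **Residual** `Rpeak / Dpeak` — the response to the ring whose inner
  diameter equals the best disk diameter, as a fraction of the best disk
  response.  Zero means the suppressive region drives nothing on its own.
* **Non-linearity index** `NLI = (max_i(D_i + R_i) - Dpeak) / Dpeak` —
  each matched disk/ring pair tiles the largest disk, so `D_i + R_i` is a
  linear prediction of the largest-disk response; NLI measures how far the
  largest prediction exceeds the best measured response.
* **Linearity index** `LI_i = 100 (Dlargest - (D_i + R_i)) / Dlargest`,
  summarised as its mean over pairs — the percent deviation of the
  measured joint response from each pair's linear prediction (negative =
  sublinear).

A sign note: the NLI is implemented as *prediction minus response over
response*.  With that orientation a linearly summating, surround-suppressed
cell has `NLI = -SI/100`, and strongly sublinear supragranular complex
cells score positive values, which is the convention used throughout the
package output (and recorded in the metric's `convention` attribute).

## Model summary

Every cortical neuron is an exponential integrate-and-fire unit
(`tau_m dV/dt = -(V - E_L) + Delta_T exp((V - V_T)/Delta_T) +
R_m g_exc (E_exc - V) + R_m g_inh (E_inh - V)`), with a spike emitted at
-40 mV, reset to -70 mV, and refractory periods of 2 ms (excitatory) and
0.5 ms (inhibitory).  Excitatory cells: `tau_m` 8 ms, `R_m` 250 MOhm,
`E_L` -80 mV, `V_T` -57 mV; inhibitory: 9 ms, 327 MOhm, -78 mV, -58 mV;
`Delta_T` 0.8 mV, `E_exc` 0 mV, `E_inh` -80 mV.  Synapses decay
exponentially (1.5 ms excitatory, 4.2 ms inhibitory) and depress following
the deterministic Tsodyks-Markram scheme with utilisation `u = 0.75` and
projection-specific recovery constants (125 ms thalamocortical, 30 ms
excitatory cortical, 70 ms layer 4 inhibitory).

Each layer contains 37,500 excitatory and 9,375 inhibitory neurons at full
scale on a 5 x 5 mm sheet mapped linearly onto the visual field (0.83
mm/deg, so the sheet spans the 6 x 6 deg LGN mosaic of 14,400
centre-surround cells).  Wiring:

* **Thalamocortical**: each layer 4 cell draws its ON/OFF afferents (per
  polarity, uniformly 45-95 for excitatory and 56-84 for inhibitory
  targets) proportionally to the positive/negative lobes of a Gabor
  profile (frequency 0.8 cpd, envelope 0.17 deg, aspect 2.5, pedestal
  0.085) whose orientation comes from a precomputed pinwheel map and whose
  phase is random; weights 1.2 nS, delays uniform in [1.4, 2.4] ms.
* **Layer 4 recurrence**: hyperbolic distance profiles
  `exp(-alpha sqrt(theta^2 + x^2))` (per-pair constants from the model's
  connectivity table) combined with a push-pull Gaussian in the pairwise
  receptive-field correlation (width 1.3, centred at +1 for excitatory and
  -1 for inhibitory sources).  RF correlations are normalised inner
  products of the cells' Gabor fields on a shared 0.1 deg grid; cells with
  disjoint fields correlate at zero.
* **Layer 2/3**: local Gaussian (sigma 270 um) plus a 4x-weighted
  long-range Gaussian (sigma 1000 um) whose long-range part is modulated
  by an iso-orientation Gaussian bias (sigma 1.3 rad); inhibition is
  purely local (hyperbolic).  Feedforward L4->L2/3 supplies 22% of layer
  2/3 excitatory input; L2/3->L4 feedback supplies 20% of layer 4
  excitatory input (both by construction of the in-degree tables).
* **Delays**: class-pair constant (1.4 ms E->E, 0.5 ms E->I, 1 ms I->any)
  plus 0.33 ms/mm of distance.

The *connectivity variants* change exactly one parameter family of the
long-range E->E connections while holding E->I fixed: spatial range 1250 um
("broad") or 740 um ("narrow") versus 1000 um, and orientation-bias width
0.7 rad ("high bias") or 3.5 rad ("low bias") versus 1.3 rad.  These are
the experiments that probe how the excitatory/inhibitory balance of
horizontal input controls the sublinearity of layer 2/3 cells.

### Design choices where the source material is ambiguous

* The printed layer 4 combined wiring rule reads as a *sum* of the
  distance and functional components; the package default combines them
  multiplicatively (`combine = "product"`, with `"sum"` retained as a
  switch).  An additive functional term would let the push-pull bias
  create sheet-spanning "local" connections, contradicting the local
  character of layer 4 wiring; the product form also matches the layer 2/3
  mixture, where the functional bias multiplies the long-range component.
* The long-range Gaussian widths are interpreted in micrometres (270 um /
  1000 um); millimetre readings would exceed the sheet itself.
* The orientation-bias Gaussian is implemented with a negative exponent (a
  proper density); a positive exponent would disfavour iso-oriented pairs.
* The L2/3->L4 feedback projection has no printed distance profile; it is
  given the layer 2/3 excitatory mixture (the same axon system as the
  intralaminar long-range connections), with the orientation bias of the
  feedforward rule.
* The degenerate protocol conditions are shared rather than re-rendered: a
  zero-diameter disk is the blank, a zero-inner ring is the largest disk,
  and the ring whose inner diameter equals the outer is the blank again.
  Apertures use the strict `r < d/2` convention so each disk/ring pair
  tiles the outer disk exactly, pixel for pixel.

### LGN front-end

LGN cells are leaky integrate-and-fire units (`tau_m` 10 ms, `R` 100 MOhm,
threshold -55 mV) driven by the space-time convolution of a
difference-of-Gaussians receptive field (centre 0.15 deg, surround
0.45 deg, surround/centre volume ratio 0.85) and a biphasic temporal
kernel (difference of unit-area alpha functions, 12 ms and 24 ms, slow
weight 0.6), plus white current noise.  None of these values are
constrained by the cortical model; they are package defaults typical of
cat X-type geniculate cells, and the noise SD is calibrated once
(`calibrate_lgn_noise()`) so the blank-screen rate matches the configured
10 spikes/s target.  The DoG is truncated at 3.5 surround sigmas; the
clipped tail changes uniform-field drives by about 0.1%.

### Numerics

Forward-Euler integration at `dt = 0.1 ms` with the exponential term
clamped (so threshold crossing is always detected) and an exact
exponential update for conductance decay.  Synaptic delays are rounded up
to the next step.  Depression resources are stored per *source* — all
outgoing synapses of a neuron share one recovery constant and one spike
history in this model, which the network compiler verifies — so the
recovery exponential is evaluated once per spike rather than once per
synapse.  Membrane potential is recorded at 1 ms; at the 2 Hz protocol
grating this oversamples the fundamental by a factor of 500.

## Stimulation and analysis conventions

The protocol presents drifting gratings (0.8 cpd, 2 Hz, full contrast, at
the orientation-map value at the sheet centre) in disks of increasing
diameter and complementary rings, 1500 ms per trial.  The temporal
frequency and contrast are not constrained by the printed model
description; 2 Hz is the typical cat V1 protocol value and both are config
entries.  Trial variability comes entirely from the LGN noise current: the
cortical integration is deterministic given the LGN spike trains, so runs
are bit-reproducible under fixed seeds, and the shuffled presentation
order (logged in the record metadata) is bookkeeping rather than dynamics,
as each condition/trial is integrated independently.

Analysis drops the first 500 ms of each trial as onset transient and
averages the remaining complete cycles (two at 2 Hz) into Vm cyclegrams
and PSTHs.  Spike removal interpolates across a 2 ms window around each
known spike time for model traces; for experimental-style traces a
dV/dt-threshold onset detector (10 mV/ms) with interpolation to
repolarisation is provided, followed in both cases by a five-point running
average.  VmDC is the cyclegram mean; VmF1 the amplitude of the free-phase
least-squares sinusoid at the fundamental (identical to the DFT
fundamental on integer-cycle windows); MFR the spikes per cycle over the
cycle duration; spikes F1 the sinusoid fit to the PSTH.  VmSD supports the
two conventions in use — per-cycle thirds, or a 100 ms sliding window —
with optional removal of the fitted fundamental (the simple-cell
convention).  Cells are classified simple if spikes F1 exceeds the mean
rate at their best disk; simple cells whose Vm depolarisation exceeds
their Vm fundamental are excluded.  Population analysis keeps cells within
0.4 deg of the field centre whose best-disk rate exceeds 1 spike/s
(strict).

## The synthetic-trace generator

`generate_synthetic_records()` emulates the *statistical shape* of the
recordings — cyclegram-structured Vm with a ratio-of-Gaussians size-tuning
profile, Gaussian noise, threshold-linear spike generation, optional
stereotyped spike waveforms — with every generative parameter known, so
the entire analysis chain can be validated for exact recovery in the
noiseless limit and calibrated recovery under noise.  It deliberately
contains no network mechanism (no conductances, no recurrence): passing
its tests certifies the analysis code path, not the biology.  The disk
profile pins the peak and largest-disk values exactly to the requested
suppression; rings decline monotonically through the requested residual,
or are exact linear complements in the `tiling_linear` variant.  F1
amplitudes are unsigned, so simple-cell fixtures should use non-negative
ring amplitudes.

## Problem sizes used by the tests and analysis scripts

Full-scale integration (s = 1, ninety-four thousand cortical neurons,
~10^8 synapses) is a cluster-sized computation.  The packaged tests and
analysis scripts run the model at reduced size, chosen as the smallest
configuration that still separates the mechanisms of interest:

* **Wiring audits**: density scale 0.06 on a 1.6 mm sheet with the
  full-scale in-degree tables, so realized in-degrees can be checked
  against the tables exactly.
* **Behavioural runs** (size tuning, laminar NLI comparison, connectivity
  variants): density scale 0.08 on a 3.83 mm sheet spanning a 4.6 deg
  field — large enough that the largest disk (4 deg) clearly exceeds the
  summation field and the long-range sigma (1 mm) is meaningfully smaller
  than the sheet — with synapses sparsified to 40% of the tabulated
  in-degrees at inversely scaled weights (`sparsify_config()`), 2 trials,
  and 7 disk diameters.  Quantitative index values at this scale are not
  expected to match full-scale values (the reduced field compresses the
  diameter axis relative to the fixed Gabor size, inflating residual
  overlap, and 2 trials leave noise-floor bias in F1 amplitudes); the
  behavioural tests therefore assert orderings and signs, not magnitudes.
* **LGN front-end**: simulated at 0.5 ms for protocol runs (the 12 ms
  temporal kernel is far slower), 0.01 ms in the closed-form f-I checks.

All scaled runs are stamped `scaled` in their provenance together with the
scale, sparsification factor, seeds and config hash.

## Known limitations

* **Reduced-scale geometry distorts the indices.**  The Gabor envelope
  (0.17 deg), the LGN centre-surround sizes and the long-range sigma
  (1 mm) are physiological constants that do not shrink with the model,
  so density-scaled runs compress the stimulus space relative to them.
  Two consequences show up consistently in the packaged runs: (i) rings
  whose inner diameter is below the Gabor support still drive simple
  cells' receptive fields directly while equally small disks drive them
  only weakly through thresholded recurrence, which inflates the
  simple-cell NLI (the inflation is signal, not estimator noise — it
  survives additional trials); and (ii) with open boundaries on a sheet
  only a few times the long-range sigma, *any* perturbation of the
  long-range excitatory-to-excitatory parameters (broader, narrower, more
  or less orientation-biased) reallocates synapses away from the
  retinotopically useful region and lowers the complex-cell NLI, so only
  the decreasing half of the variant effects reproduces at desk scale.
  The behavioural tests therefore treat surround suppression, the laminar
  NLI ordering and the decreasing variant inequalities as the reduced
  model's reproducible signatures; recovering the increasing variant
  inequalities and the absolute index values requires the full-scale
  sheet and synapse counts.
* No feedback from higher visual areas and no explicit infragranular
  layer: the infragranular hypothesis is probed, as in the source model,
  through the long-range connectivity variants of layer 2/3.
* Surround suppression of the *membrane potential* is weak in the model
  (spiking suppression is strong); absolute LI magnitudes are
  correspondingly smaller than in vivo.
* One inhibitory population per layer; no cell-type diversity.
* Single-orientation protocol only — no cross-orientation surround,
  contrast series, or natural images.
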