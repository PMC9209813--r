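---
title: "Fast-scan circular photoacoustic tomography: simulation, reconstruction, and learned restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-scan circular photoacoustic tomography: simulation, reconstruction, and learned restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patkit)
```

## The problem

In circular-scan photoacoustic tomography (PAT) a pulsed laser deposits
energy in optical absorbers; the resulting thermoelastic pressure launch
is recorded as time series (A-lines) by one or more ultrasound
transducers (USTs) rotating around the sample, and a beamformer turns
the stacked A-lines (the sinogram) into a cross-sectional image of the
initial pressure. With a single transducer and a 10 Hz laser, a
well-sampled revolution takes minutes; scanning faster means fewer
A-lines per revolution and lower per-pulse energy, so fast scans suffer
streaking artifacts and low SNR. `patkit` implements an end-to-end
workbench for this regime: synthetic phantoms, a fast analytical forward
simulator, delay-and-sum (DAS) reconstruction, and a hybrid dense U-Net
(HD-UNet) trained to map sparse-view, low-SNR reconstructions to
dense-scan quality, together with the evaluation protocol and an ANSI
laser-safety calculator.

Two stock system presets are provided. The single-transducer preset
(`pat_preset("1ust")`) models a 2.25 MHz unfocused UST (70% nominal
bandwidth, 13 mm active element) at 10 Hz pulse repetition rate on an
82 × 82 mm grid at 0.2 mm/pixel; sparse inputs use 10–50 detector
positions (1–5 s of scanning) at 40 dB SNR and ground truth uses 4800
positions with a point detector. The eight-transducer preset
(`"8ust"`) models eight 5 MHz USTs at 2000 Hz on a 0.1 mm/pixel grid;
fast scans use 240 positions (0.3 s), SNR drawn uniformly from 10–20 dB,
and ground truth uses 1600 point-detector positions. The imaging region
is a centered 40 mm disc in both cases; the medium is homogeneous with
c = 1500 m/s; A-lines are 1500 samples at 40 ns.

## Forward model

For a homogeneous lossless medium the pressure at a point detector can
be written through circular means of the initial pressure `p0`:

    p(r_d, t)  ∝  ∂/∂t [ t · M(p0)(r_d, ct) ],

where `M(p0)(r_d, ρ)` averages `p0` over the circle of radius ρ around
the detector. Discretizing `p0` as pixel point sources collapses
`t · M(ct)` to a weighted histogram of arrival times `|x_k − r_d|/c`
(the `1/(2πρ)` of the circular mean cancels against the leading `t`),
which we bin with linear interpolation, differentiate by central
differences, and convolve with the transducer's electrical impulse
response (EIR). This operator is exact for the stated physics, linear,
and fast enough to synthesize thousands of scans on a desktop — it
replaces a full pseudospectral wave solver, which is out of scope here.
The practical differences are discussed under *Limitations*.

Numerical choices:

* **EIR** — a zero-phase Gaussian-modulated sinusoid whose amplitude
  spectrum peaks at the central frequency with a −6 dB fractional width
  equal to the nominal bandwidth (0.7), normalized to unit peak spectral
  magnitude. An `ideal` transducer is a point detector with a delta
  response; the ground-truth presets use a *band-limited point*
  detector (aperture 0 but finite bandwidth), matching how dense
  reference scans are specified for these systems.
* **Aperture** — a flat 13 mm element tangent to the scan circle,
  integrated segment-wise: each of 33 sub-segments deposits its
  arrival-time spread as a uniform box over the covered time bins.
  Box integration converges quadratically in the segment count (point
  sub-element sampling converges only linearly and would need hundreds
  of elements); at the default 33 segments, doubling the count changes
  the sinogram by about 0.25% rms.
* **SNR** — rms-based, `20 log10(rms_signal/rms_noise)` over the whole
  sinogram, with seeded white Gaussian noise.
* **Scan planning** — `positions_per_ust = round(duration × prr /
  averaging_factor / n_ust)`, each transducer sweeping its own equal
  angular sector. The eight-transducer preset uses an averaging factor
  of 2.5 so planned counts match the stored A-line counts of that
  hardware (240 positions for 0.3 s, 1200 for 1.5 s at 2000 Hz).
* **Scan radius** — 37 mm by default: outside the 40 mm imaging disc
  with clearance, inside the 82 mm grid. The time window (60 µs)
  comfortably covers the farthest arrivals (~38 µs), so the circular
  FFT convolution used for the EIR cannot wrap signal into the record.

## Phantoms

Three seeded generator families emulate the training corpus:

* **Point targets** — `n` discs of 0.5 mm diameter (a pencil-lead
  cross-section) at non-overlapping random positions, each with an
  independent strength in [0.5, 1]. Placement retries are capped
  (default 1000) and exhausting them is an error.
* **Triangles** — a thin (1 pixel) equilateral outline with random
  side length (10–25 mm), rotation, and center, kept fully inside the
  imaging disc; a filled variant is available behind a flag.
* **Vessels** — a procedural stand-in for the cerebral venous sinuses
  of the rodent brain: one smooth low-order curved trunk spanning the
  disc plus 2–6 lateral branches at random angles, each drawn with a
  0.3–1.0 mm cross-section and independent magnitude in [0.5, 1], with
  global random rotation and translation.

Strength ranges, the point diameter, and the vessel statistics are
package defaults chosen to look like the corresponding physical
phantoms; none of them is prescribed by the systems being modeled, and
all are configurable. Every generator is a pure function of
`(grid, parameters, seed)` and places all mass inside the 40 mm disc.

## Reconstruction and pairing

DAS is deliberately plain: `I(x) = Σ_d s_d(|x − r_d|/c)` with linear
interpolation between time samples, no apodization and no solid-angle
weighting; delays outside the record contribute zero. Output images are
128 × 128 over the 40 mm field of view (0.3125 mm pitch). Images are
normalized by the min–max map `(A − Amin)/(Amax − Amin)`, which keeps
the bipolar information as an offset (zero pressure lands at
`−Amin/(Amax−Amin)`) instead of clipping it. The ground truth of a
training pair is itself a DAS reconstruction — of the dense, noise-free,
point-detector scan — not the raw phantom, so the network learns
artifact removal rather than deconvolution of the imaging chain.

## The HD-UNet and its baselines

All four architectures share a four-level encoder–decoder skeleton for
1-channel 128 × 128 images (any size divisible by 8 works; a strict
shape flag can pin 128). At level `l` the feature target is
`fl = 2^(l−1)·fi` and the dense growth rate `kl = 2^(l−1)·8`. A dense
block runs `fi/8` steps; each step consumes the concatenation of
everything before it and emits `kl` new channels, so the block's output
has exactly `2·fl` channels. Down-transitions are a 1 × 1 convolution
block projecting to `f(l+1)` followed by a stride-2 3 × 3 convolution
block; up-transitions are transposed stride-2 3 × 3 convolutions. Every
convolution block is convolution → batch normalization → ReLU. The head
is a 3 × 3 block back to `fi` channels and a final 3 × 3 convolution to
1 channel with a bias and a ReLU (targets live in [0, 1]; no batch norm
on the output).

Variant differences:

* **hd** — dilated dense blocks in the encoder (each step splits `kl`
  into equal halves at dilation 1 and dilation 2; the rate is capped at
  2 to limit gridding artifacts), standard dense blocks in the decoder,
  and a residual bridge (two 3 × 3 blocks with an identity shortcut) at
  the bottleneck.
* **fd** — standard dense blocks in both paths, no residual bridge.
* **dd** — the parameter-hungry dilated baseline: dense steps stack
  dilation rates 1, 2 *and* 4 at full `kl` each, in both paths. Its
  exact internal structure is not fixed by the systems we compare
  against; this choice reproduces the two properties the comparison
  rests on — a much larger parameter count at equal `fi` and a larger
  (but gridding-prone) receptive field.
* **unet** — plain double-convolution blocks in both paths.

Open design points we fixed (and why): `fi` defaults to 32 (the FD-UNet
lineage; desk-scale tests use 16 or 8); skip connections concatenate the
encoder *level input* (`fl` channels), which keeps the decoder ledger
self-consistent (`transposed conv → fl`, concat → `2·fl`, dense entry
1 × 1 back to `fl`, steps grow to `2·fl`); the phrase "batch
normalization preceded by convolution and RELU activation" is read in
the standard order convolution → BN → ReLU; weights use seeded He
(fan-in) initialization. `receptive_field()` composes kernel extents,
dilations and strides analytically — replacing dilation 2 by 1
everywhere strictly shrinks the bottleneck receptive field, which is
the design argument for the hybrid split.

The engine behind the networks is a small reverse-mode tape built for
this package: im2col/shift-GEMM convolution kernels (C++, BLAS-backed),
fused batch-norm/ReLU, transposed convolutions as the adjoint of the
stride-2 convolution, and an in-place Adam. Gradients are verified
against central finite differences in the test suite.

## Loss and metrics

Training minimizes `L = k1·L_MAE + k2·L_FMAE` with `k1 = 1`,
`k2 = 0.001`. `L_MAE` is the pixel mean absolute error. `L_FMAE` is the
mean complex modulus of the difference of *unnormalized* 2D DFTs — the
convention is pinned by an analytic anchor in the tests: if
`Yg − Yp = c` everywhere then `L_FMAE = |N·c|/N = c` exactly. The small
`k2` keeps the frequency term a regularizer; it is known to destabilize
training when weighted strongly.

Evaluation reports per-image Pearson correlation (PCC), SSIM (uniform
7 × 7 window, data range 1, standard stabilization constants), PSNR
(data range 1, capped at 100 dB for identical images), and MAE,
summarized as mean ± sd. Constant images have undefined PCC; such pairs
are excluded from the PCC summary and counted in a warning.

## Training protocol

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) at an initial learning rate of
0.001, halved after 5 epochs without validation-loss improvement
(floor 1e−6), 100 epochs, batch size 2, on a 90:5:5
train/validation/test split. The monitored quantity is the validation
composite loss; early stopping is not used. Repeated cross-validation
(`cross_validate()`) performs 10 independent random resplits — the
protocol is repeated random resplitting rather than disjoint-fold
partitioning, and the report names them "repeats" accordingly — with a
fresh split and fresh networks per repeat, aggregating mean ± sd per
architecture.

## Problem sizes in the shipped tests

The full-scale experiment (1500 simulated pairs, `fi = 32`, 100 epochs,
10 repeats, all four architectures; `full_scale_config()`) is a
multi-day CPU computation. The package's own test suite exercises the
identical code path at desk scale, a deliberate package choice: 100
simulated single-UST pairs, HD-UNet at `fi = 16`, 10 epochs, batch 2,
fixed seeds. At that scale the trained network must already improve
held-out SSIM and PSNR over the sparse DAS inputs, which is the
meaningful desk-scale surrogate for the full comparison table.
Unit-level checks run on 16–64 pixel images and tiny scans.

## Limitations and honest findings

* **Forward-model substitution.** The analytical circular-mean operator
  shares the physics of a homogeneous lossless 2D medium with a
  pseudospectral solver but not its numerical dispersion, perfectly
  matched layers, or grid staircasing. Quantities that depend on fine
  waveform detail (absolute loss values, PSNR in dB) will differ from
  pipelines built on a wave solver; comparative statements (metric
  orderings across architectures and scan densities) are the intended
  use.
* **What the generator does not emulate.** Optical fluence variation,
  acoustic heterogeneity and attenuation, transducer focusing, 3D
  out-of-plane signal, and real EIRs measured from hardware. Passing
  desk-scale tests demonstrates the pipeline's internal consistency,
  not performance on in vivo data.
* **SSIM vs scan density is not monotone at the sparse end.** Under
  this simulator and the stock normalization, mean SSIM between sparse
  inputs and dense ground truth *dips* between ~10 and ~50 positions
  before rising toward 1 at dense sampling: with very few detectors the
  image is mostly flat background, and SSIM's luminance/structure terms
  reward that flatness more than they reward a denser but still
  streak-filled image. PSNR behaves monotonically on average. The test
  suite records this property as measured; restoring monotonicity would
  require a contrast-aware metric or masked SSIM, which we deliberately
  did not substitute.
* **Bipolar images.** DAS outputs are bipolar; no envelope or Hilbert
  processing is applied (multiview Hilbert DAS is explicitly out of
  scope), so "background" sits at the normalized zero offset, not at 0.
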