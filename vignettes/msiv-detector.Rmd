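---
title: "Spiral information-vortex feature decoupling for dense canopy detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiral information-vortex feature decoupling for dense canopy detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivyolo)
```

## The problem

UAV imagery of rice paddies poses a particular detection regime: the targets
(panicles, tillers) are small, elongated, densely packed and heavily
overlapping, and the background carries structured clutter — dappled light,
soil-clod shadows, specular reflections from residual water film. A
conventional one-stage detector sees "adhered" features: activations from
neighbouring plants blur together, and background clutter correlates with
plant texture. `ivyolo` implements a detector built around an operator
designed for exactly this regime: the **Multi-scale Spiral Information
Vortex (MSIV)**, embedded in a progressive feature-fusion neck (**GFEN**),
with a YOLO-style anchor-free multi-scale head.

## The MSIV operator

MSIV transforms a feature map $F \in \mathbb{R}^{H \times W \times C}$ into
an equally-shaped map through four stages, each motivated by the image of a
water vortex "grooming" a rice canopy: rotate, reorganize, separate, fuse.

**1. Rotated multi-scale kernel bank.** $K$ groups of fixed depthwise
kernels are built (default $K = 3$ with sizes $s_k \in \{3, 5, 7\}$). Group
$k$ carries an anisotropic 2-D Gaussian whose major axis is rotated by the
vortex angle

$$\theta_k = \mathrm{clamp}\!\left(\alpha \cdot \frac{k\pi}{2K},\; 15^\circ,\; 60^\circ\right),$$

with the angle coefficient $\alpha \in [0.5, 1.5]$ (default 1.0; a seeded
uniform draw from that interval is available via `alpha_random`, fixed at
construction — never per forward pass, which would break determinism). The
anisotropy is $\sigma_\text{major} = s_k/3$, $\sigma_\text{minor} = s_k/6$;
an isotropic Gaussian would make the rotation unobservable. Kernels are
normalized to sum to one and are *buffers*, not trainable parameters.

**2. Rotational residual convolution.** Each branch computes
$F_k = \mathrm{DWConv}(F, V_k) + F$ with "same" padding $s_k \,\mathrm{div}\, 2$,
so shapes are preserved and the residual guarantees that rotational
smoothing can never erase the original signal (a zero kernel gives the
identity exactly — one of the package's tested invariants).

**3. Channel–spatial reorganization.** The spiral channel step computes a
per-pixel integer shift $\lfloor i\sin\theta_k + j\cos\theta_k\rfloor \bmod C$
(non-negative, 0-based pixel indices) and cyclically rotates each pixel's
channel vector by it. The original formulation indexes a *single* channel
and broadcasts it across the whole vector; that collapses channel diversity
to one value per pixel, so the package defaults to the information-preserving
cyclic shift and keeps the broadcast behind
`channel_reorg_mode = "literal_broadcast"` for fidelity. The spatial step
applies a position-dependent rotational offset
$\Delta i = \beta_\text{eff}(i - H/2)(j - W/2)\sin\theta_k$ (and
$\cos\theta_k$ for $\Delta j$) followed by bilinear resampling with
border-clamped coordinates. The raw product $(i - H/2)(j - W/2)$ grows with
the map area, which would tear large maps apart, so the package normalizes
$\beta_\text{eff} = \beta / (HW/4)$: the corner of the map moves by about
$\beta$ pixels at any resolution. The default $\beta = 2$ therefore means
"up to two pixels of vortex shear", a perturbation strong enough to separate
adhered activations yet below the scale of the objects themselves.
$\beta = 0$ recovers the exact identity (tested).

**4. Attention fusion and DyT.** The $K$ reorganized branches are summed,
global-average-pooled to a $C$-vector, passed through a learnable linear map
$C \to K$ and a sigmoid, yielding one weight per scale in $(0,1)$; the
output is the weighted sum of branches, followed by one **Dynamic Tanh**
layer $\mathrm{DyT}(x) = \gamma_c \tanh(\alpha x) + \beta_c$ — the
normalization-free substitute for a norm layer, bounding each channel to
$[\beta_c - |\gamma_c|,\, \beta_c + |\gamma_c|]$. The linear projection is a
design choice the original formulation leaves open (its pooled vector is
$C$-dimensional but the weight vector is $K$-dimensional); a
squeeze-excitation-style projection is the minimal learnable bridge. The
attention projection and DyT are the only trainable parts of an MSIV block
(about $KC + K + 2C + 1$ scalars).

Both reorganization stages are verified against brute-force per-pixel scalar
oracles (`oracle_channel_reorganize`, `oracle_spatial_reorganize`) written
without shared code, and the composed `msiv_forward` is verified to be
bit-identical to chaining the five exported stage functions.

## Detector assembly

The backbone is a five-stage strided hierarchy of `Conv(k=3, s=2)` + C3K2
blocks (a CSP-style split/bottleneck/concat/fuse block; the source material
uses the names C3K2 and C3X2 interchangeably and the package implements one
block for both), with an MSIV block closing each of the three deepest
stages. Feature maps are tapped at strides 8/16/32.

The GFEN neck fuses bottom-up in two stages: MSIV-enhance the stride-8 and
stride-16 maps, downsample the former (stride-2 conv), concatenate, fuse
with C3K2 (`Ffusion1`); then repeat with `Ffusion1` and the stride-32 map
(`Ffusion2`). The three head inputs are the MSIV-enhanced stride-8 map,
`Ffusion1` and `Ffusion2`. Resolution matching uses stride-2 convolutions
downward and nearest-neighbour upsampling where the plain neck needs it.
Exact stage layout within the backbone (how many C3K2 blocks per stage,
where MSIV intervenes) is recorded here as the package's choice, not claimed
canonical; neck MSIV blocks do not share parameters with backbone ones.

Two ablation switches reproduce the reduced topologies: `use_msiv = FALSE`
removes every MSIV block (identity in its place — the parameter count
strictly decreases), and `use_gfen = FALSE` swaps in a plain top-down
upsample–concat–C3K2 neck.

At the published scale (base channels 16/32/64/128/256, one bottleneck per
C3K2, head hidden width 120, one class, 640-px input) the detector carries
**2,520,027 trainable parameters ≈ 2.52 M**; `scripts/acceptance.R`
recomputes this. The head hidden width is the knob that was tuned once to
land the total at the reported scale; it is recorded in
`ivyolo_config()` defaults.

## The training engine

No automatic-differentiation framework is used: the package ships its own
small CPU engine. Convolutions run through compiled im2col/GEMM kernels
(RcppArmadillo); each layer implements a hand-derived backward pass, all of
which are tested against central finite differences to ~1e-6. Because the
network has no normalization layers, two numerical choices matter:

* **Initialization.** SiLU has small-signal gain ≈ 0.5, so He
  initialization would halve the activation scale at every layer and a
  12-layer backbone would collapse to ~1e-3 of its input scale. Conv weights
  are therefore drawn with $\sigma = 2/\sqrt{\text{fan-in}}$, and the input
  image is standardized from $[0,1]$ to roughly zero mean and unit scale.
* **Optimization.** Adam with global gradient-norm clipping (threshold 5).
  Clipping is what keeps a constant learning rate of 1e-2 stable; without it
  the loss exhibits intermittent spikes. A cosine decay to one tenth of the
  base rate is available and is the default schedule of `ivyolo()`.

The loss is a standard anchor-free composite: each ground-truth box is
assigned to the grid cell containing its centre at the scale matched to its
size (size thresholds $H/8$ and $H/4$ pixels route targets to strides
8/16/32); positives incur an IoU loss plus a small L1 pull (weight 0.4) on
the raw box parameters — the L1 term supplies gradients when a prediction
does not yet overlap its target, where the IoU gradient vanishes — and all
cells incur binary cross-entropy on the class logits with positive cells
weighted 3×. Box centres use the symmetric $2\sigma(t) - 0.5$
parametrization. An optional denser three-cell assignment exists
(`neighbor_cells = TRUE`) but is off by default: in experiments it tripled
confident near-duplicate detections and cost precision faster than the
extra supervision helped.

Degenerate (zero-area) targets are skipped with a warning; `exp` size
decoding is clamped at $e^8$; bilinear sampling clamps coordinates to the
map border; equal-score detections keep their pre-sort order (stable sort)
in matching and NMS.

## Synthetic scenes: what they emulate, and what not

The generator renders rotated elongated ellipses ("plants") with
per-instance hue jitter over a textured ground plane, with three clutter
families taken from the field-interference taxonomy: dark shadow polygons,
bright specular specks, and pixel noise. A placement rule drives overlap
(each new plant attaches next to an existing one with probability
`overlap_target`), and the `gsd_level` setting scales plant size by
1.0/0.6/0.35 to emulate the three capture-altitude regimes of UAV surveys
(coarser ground-sample distance ⇒ smaller objects; the median box area
ordering is a tested property). Boxes are tight axis-aligned hulls of each
ellipse, written in YOLO normalized `class cx cy w h` format at six
decimals. Everything is a pure function of (configuration, seed); pixels are
quantized to 8-bit so PNGs round-trip exactly.

What the synthetic scenes do *not* have: real panicle morphology (awns,
curvature), perspective and motion blur, growth-stage appearance variation,
inter-image illumination statistics of real UAV campaigns. Passing the
package's training tests therefore demonstrates that the architecture,
gradients, optimizer and metrics interoperate correctly end to end — it does
not certify detection accuracy on real paddy imagery.

## Problem sizes used by the test suite

The suite verifies oracle equivalence on 50 random fixtures with
$H, W, C \le 16$; unit gradients on maps of about $6^2$–$8^2$ cells; and the
end-to-end trainability property on 8 synthetic scenes of 320×320 px with
25 plants each, fit with a width-0.25 detector (~162 k parameters) for at
most 300 full-batch Adam steps at a constant learning rate of 1e-2,
stopping as soon as training-set AP50 reaches 0.9 (typically near step 150).
These sizes were chosen as the smallest at which each property is
meaningfully exercised.

## Metrics

The evaluation module implements the COCO conventions: greedy score-ordered
one-to-one matching (ties toward the lower ground-truth index), 101-point
interpolated average precision, AP as the mean over IoU 0.50:0.95 in steps
of 0.05, and AP50/AP75 at fixed thresholds. Precision and recall are
reported at a confidence threshold (default 0.25, with IoU-0.5 matching);
precision with zero retained detections is defined as 0, and the report also
records the maximum-F1 operating point because the default threshold is
arbitrary. The feature-purity diagnostic — the ratio of mean per-pixel
channel-L2 response inside a target mask to that outside — is provided as a
qualitative probe of the decoupling effect; its original measurement
protocol (which layer, which masks) is unspecified, so the package makes no
quantitative claim about it.

## Known limitations

* The engine is single-image (no batched tensors); throughput is adequate
  for desk-scale experiments, not for full-dataset training.
* `literal_broadcast` channel mode is forward-only (not trainable): it
  exists to expose the behaviour of the original formulation, which is
  information-destroying by construction.
* The task-aligned assigners of modern YOLO variants are out of scope; the
  centre-cell assigner is the simplest correct choice for an anchor-free
  head.
* Benchmark-scale accuracy claims require the real UAV dataset and
  GPU-scale training, both outside this package's scope.
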