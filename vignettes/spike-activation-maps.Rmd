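---
title: "Spike activation maps: gradient-free visual explanations for spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike activation maps: gradient-free visual explanations for spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spiking neural networks (SNNs) process images as binary spike trains unfolding
over discrete time-steps. Their units — leaky integrate-and-fire (LIF)
neurons — are non-differentiable, so the gradient-based saliency tools of
conventional deep learning (Grad-CAM and relatives) only apply through
*surrogate* derivatives, and the approximation error compounds layer by layer
into blurred, non-discriminative heatmaps (a "heatmap smoothing effect").

This package implements a different route: the **spike activation map (SAM)**,
a visual explanation computed entirely in the forward pass, with no gradients
and no class label. It rests on the neuroscience observation that spikes
arriving with short inter-spike intervals (ISI) carry more information,
because they are more likely to drive post-synaptic neurons above threshold.

## The model

### LIF dynamics

Each hidden layer runs the soft-reset discrete LIF recurrence

$$u_t = \lambda\, u_{t-1} + d_t - \theta\, o_{t-1}, \qquad
  o_t = \mathbb{1}[u_t > \theta],$$

where $d_t$ is the weighted pre-synaptic drive, $\lambda \in [0,1]$ the leak
and $\theta > 0$ the firing threshold. The printed recurrence in the source
material indexes the spike decision ambiguously (the reset consumes
$o_{t-1}$ while the spike rule is written at $t-1$); we adopt the one
consistent single-pass reading: integrate, decide the spike from the fresh
potential, apply the reset at the next update. Potentials start at zero (the
conventional rest state; initialization is otherwise unspecified). The output
layer is a pure accumulator ($\lambda = 1$, $\theta = \infty$): its final
potentials are the logits summed over all $T$ steps.

Static images enter through Poisson rate coding: independently per pixel and
step, a spike is emitted with probability $p/255$ for intensity $p$, so
expected spike counts are proportional to intensity. (The source text's
verbal description of the sampling rule contradicts its own proportionality
statement; we implement the proportional convention.)

### SAM

For every neuron we keep a **neuronal contribution score** (NCS): the sum of
an exponential ISI kernel over the neuron's strictly-previous firing times
$P$,

$$T(t, t') = e^{-\gamma |t - t'|}, \qquad
  N_t = \sum_{t' \in P,\ t' < t} T(t, t').$$

Because the kernel is exponential, the set sum collapses to the running
recursion $N_t = e^{-\gamma}(N_{t-1} + s_{t-1})$, which the implementation
uses; a brute-force set-sum oracle in the test suite confirms the
equivalence to $10^{-9}$. The per-time-step heatmap is the channel sum of
NCS times current spike activity,

$$M_{ij,t} = \sum_k N^k_{ij,t}\, S^k_{ij,t},$$

computed in one forward sweep. The steepness $\gamma \ge 0$ is the only
tunable: $\gamma = 0$ degenerates to a previous-spike count, large $\gamma$
to a one-step memory. The default is $\gamma = 0.2$, a mid-range value
between those two failure modes (no specific value is prescribed by the
method; the CLI exposes `--gamma`).

Heatmap sequences are normalized to $[0,1]$ by the single global maximum
across all time-steps of a sample (default), which keeps the temporal
evolution comparable across steps; per-time-step normalization is available
via `normalize_heatmaps(per_timestep = TRUE)`.

### Baselines

*SNN-crafted Grad-CAM* backpropagates the target-class logit through time
with a triangular surrogate derivative (peak 1 at $u = \theta$, half-width
$\theta$ — the common threshold-scaled choice, since the cited piecewise
linear surrogates come without parameters), accumulates
$\alpha^{c,k} = \frac{1}{N}\sum_{i,j,t} \partial y^c / \partial A^k_{ij,t}$
with $N = T H W$, and forms $G_t = \max(0, \sum_k \alpha^{c,k} A^k_t)$. The
equations are inconsistent about whether $\alpha$ is per-time-step
(subscript $t$ appears on one side only); we follow the summed, \
time-independent form. The backward pass includes the reset path (the spike's
effect on the next potential), matching what a reverse-mode autodiff of the
recurrence would produce.

*ANN Grad-CAM* on a reference ReLU network of identical topology provides
the localization reference $G$: channel weights are global-average-pooled
gradients, the map is the ReLU of the weighted activation sum, normalized to
$[0,1]$.

### Training and conversion

Surrogate training uses SGD (momentum 0.9, weight decay $5 \times 10^{-4}$,
10$\times$ step decay at 50/70/90% of the epoch budget — mirroring the usual
recipe) on the cross-entropy of the accumulated potentials, with **batch
normalization through time** (BNTT): per-channel, per-time-step statistics
and a learnable scale, no additive shift. Running statistics use an
exponential moving average with momentum 0.1 (standard batch-norm practice;
unspecified in the source). Hidden leak defaults to 0.99 for surrogate
training, 1.0 for conversion.

ANN-to-SNN conversion copies the ANN weights and sets each layer's firing
threshold, layer by layer from the input side, to the maximum pre-activation
observed while running Poisson-coded calibration inputs (64 by default; the
calibration set size is unspecified in the source) through the partially
converted network.

## The desk-scale testbed

The method was originally demonstrated on VGG11/Tiny-ImageNet, which is far
outside a single-CPU budget. The synthetic stand-in is deliberately small
and fully specified:

* 16×16 single-channel images, 4 balanced classes, each class a distinct
  high-intensity glyph (disk, ring, bar, cross) at intensity $200 \pm 20$,
  placed at a random position and scale over uniform background noise in
  $[0, 0.3 \cdot 255]$. The binary ground-truth mask marks glyph pixels and
  always covers 5–40% of the image.
* 300 training and 100 test images; a 3-conv network (8/16/16 channels,
  average pooling, global average pooling, linear accumulator); $T = 20$ for
  surrogate training, $T = 128$ for the converted network.
* Noise level 0.3 keeps Poisson rates discriminative at $T = 20$ (glyph rate
  ≈ 0.78/step vs background mean ≈ 0.15/step) while leaving genuine
  background spiking for the ISI kernel to filter.

What the generator does **not** emulate: natural-image statistics, texture,
occlusion, class-internal appearance variability, and depth (3 conv layers
vs 8+). A green test on this testbed establishes that the machinery is
correct and that the stated trend is reproducible *at this scale* — not that
the corresponding figure-level claim holds in general.

## Numerical choices

* Localization error is the standard non-negative binary cross-entropy
  between the SAM sequence and the reference map, minimized over time-steps.
  (The printed formula omits the conventional minus sign; we negate it, since
  as printed the "minimum" would select the worst-matching step.) Maps are
  clamped to $[\delta, 1-\delta]$, $\delta = 10^{-6}$, before logarithms, and
  the reference is resized (corner-aligned bilinear) to each probed layer's
  resolution, preserving the map's native granularity.
* All-zero heatmap sequences normalize to all-zero, and
  `mask_localization_score` defines 0 for them.
* FGSM against the SNN differentiates the loss w.r.t. the analog image that
  parameterizes the Poisson rates (sampled spikes are not differentiable);
  raw input gradients are summed over all time-steps and the sign is taken
  once.
* BNTT train mode uses population (biased) batch variance, matching standard
  batch-norm.

## Design choices that were genuinely open

* **Probe layers.** Mask localization uses the shallowest conv layer (native
  16×16 resolution, directly comparable with the pixel mask). Comparisons
  against Grad-CAM references use either all three conv layers averaged (the
  γ sweep; mirroring the original per-layer panels) or the deepest conv
  layer (the adversarial comparison; the canonical Grad-CAM target).
* **Conversion calibration data**: the first 64 training images (whether the
  original used train or test data is unstated; configurable).
* **Average pooling on spikes** may emit fractional values that feed the next
  layer's drive; this preserves rate information (pooling behavior on spike
  trains is otherwise unspecified).
* **Array container**: checkpoints, rasters and heatmaps are stored as a
  single compressed RDS bundle of named arrays plus a structured manifest —
  the natural portable container in an R-only toolchain. Plain-text ASCII
  PGM/PPM stand in for PNG in image I/O, keeping the package free of binary
  format dependencies.

## Known limitations

Three scale-dependent trends from the original study do **not** reproduce on
this desk-scale testbed, and their acceptance tests are intentionally left
failing rather than weakened (see the repository's decision ledger):

* the γ-sweep's γ = 0 arm (at 3 conv layers and T = 20 the flat-kernel map
  is statistically indistinguishable from the mid-γ map; errors differ by
  < 2%, in the wrong direction);
* the variance advantage of SAM over SNN-crafted Grad-CAM at the shallowest
  layer (the smoothing effect needs many stacked surrogate layers to
  accumulate);
* the rise-and-fall temporal spike profile of surrogate-trained networks
  (our BNTT scales stay nearly flat over 20 steps on an easy task, while the
  converted network's charging ramp gives it the *higher* temporal
  coefficient of variation at T = 128).

The adversarial comparison (SAM sequences changing less under FGSM than ANN
Grad-CAM maps, and monotone accuracy degradation with ε) does hold on the
testbed, but only narrowly for the L1 part; treat it as fragile at this
scale.

These are properties of depth and task scale, not of the algorithms: the
implementations are validated independently by exact oracles (set-sum NCS,
finite-difference gradients, closed-form metrics) in the unit suite.

## A minimal session

```{r, eval = FALSE}
library(spikesam)

ds <- make_shape_dataset(n_classes = 4, image_size = 16, n_per_class = 100,
                         noise_level = 0.3, seed = 20210924)
fit <- train_snn(ds, cfg = train_config(epochs = 30, lr = 0.02,
                                        timesteps = 20, seed = 2))

img <- array(ds$images[, , , which(ds$split == "test")[1]], c(1, 16, 16))
raster <- poisson_encode(img, 20, seed = 1)
fw <- forward_network(fit$config, fit$weights, raster, record_layers = 1)
sam <- normalize_heatmaps(compute_sam(fw$records[["1"]], gamma = 0.2))

mask_localization_score(sam, ds$masks[, , which(ds$split == "test")[1]])
```
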