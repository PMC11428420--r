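---
title: "Unpaired low-dose CT denoising: model, training protocol, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired low-dose CT denoising: model, training protocol, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacdenoise)
```

## The problem

Low-dose CT (LDCT) reduces radiation exposure at the cost of a lower
signal-to-noise ratio: lower tube current (mA) means fewer photons, more
quantum noise, and — at very low doses — directional streak artifacts.
Paired supervision (the same anatomy scanned at both doses) is rarely
available, so denoising is cast as *unpaired* image-to-image translation
between a low-dose domain $X$ and a standard-dose domain $Y$: two
generators, $G: X \to Y$ and $F: Y \to X$, are trained adversarially
against discriminators of each domain, with cycle-consistency
($F(G(x)) \approx x$, $G(F(y)) \approx y$) and identity
($G(y) \approx y$, $F(x) \approx x$) penalties supplying the supervision
that paired data would otherwise give.

## The generator

The translation network is a two-down/two-up convolutional
encoder–decoder with three deliberate substitutions relative to the classic
residual CycleGAN generator:

* **Anti-aliased down-sampling.** Every down-sampling step is a *blur-pool*:
  a normalized binomial low-pass filter (default $3\times3$,
  $\tfrac{1}{16}[1\,2\,1]^\top[1\,2\,1]$) under reflection padding followed
  by stride-2 subsampling. No bare strided convolution or max-pool appears
  anywhere (asserted structurally by the tests). Blurring before subsampling
  suppresses aliasing, making the features approximately shift-equivariant.
* **Sub-pixel up-sampling.** Decoding uses pixel shuffle: a convolution
  expands channels by $r^2$ and a lossless rearrangement moves them into an
  $r\times$ larger grid. This avoids the checkerboard artifacts of
  transposed convolutions. $r = 2$ per stage is required so that
  $r^{n_\mathrm{down}}$ exactly undoes the encoder's $2^{n_\mathrm{down}}$
  down-sampling.
* **HFS residual core with scSE gates.** The bottleneck stacks *hierarchical
  feature synthesis* modules: three residual blocks run in sequence, their
  residual-branch outputs are concatenated with the final trunk ($4C$
  channels), fused back to $C$ channels by a $1\times1$ convolution, and
  added to the module input. With a zero-initialized fuse convolution the
  module is exactly the identity — a property the tests assert. Each
  residual branch ends in a concurrent spatial and channel
  squeeze-excitation (scSE) gate: a channel gate (global average pool →
  bottleneck → sigmoid) and a spatial gate ($1\times1$ convolution →
  sigmoid), combined elementwise (default `max`; `add`/`multiply` are
  exposed for ablation, as are the single-branch `cse`/`sse` arms).

Encoder convolutions are spectrally normalized (one power-iteration step per
training forward; gradients treat the singular vectors as constants, the
standard practice) and instance-normalized. The head and tail are
reflection-padded $7\times7$ convolutions; the tail ends in a sigmoid so
outputs live on the same $[0,1]$ scale as min-max-normalized inputs.

## The discriminators

Each domain is judged by a bank of three patch discriminators at full, half
and quarter resolution ($512/256/128$ at training scale). By default the
smaller scales are random native-resolution crops (a pyramid of blur-pooled
down-scalings is available behind `input_mode = "pyramid"`). Each
discriminator stacks stride-1 spectrally normalized $4\times4$ convolutions
followed by blur-pool down-sampling; only the first block carries batch
normalization. The final stage zero-pads one row on top and bottom (rows
only — implemented literally as printed) and applies a $4\times4$ stride-1
convolution to one channel, so a square input yields a non-square score
map. Block convolutions use reflection padding so that flat regions stay
flat; the printed rows-only zero padding is reserved for the final stage.

## The objective

With probability-form scores $D_i(\cdot) \in (0,1)$ clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-7}$:

$$\mathcal{L}_{GAN}(G, D_{i,Y}) = \frac{1}{N}\sum_{i=1}^{N}
\big[\mathbb{E}_y \log D_{i,Y}(y) +
\mathbb{E}_x \log(1 - D_{i,Y}(G(x)))\big], \qquad N = 3,$$

plus the mirror-image term for $F$ and $D_{i,X}$; cycle consistency
$\mathcal{L}_{cyc} = \mathbb{E}\|G(F(y)) - y\|_1 +
\mathbb{E}\|F(G(x)) - x\|_1$; identity
$\mathcal{L}_{idt} = \mathbb{E}\|G(y) - y\|_1 + \mathbb{E}\|F(x) - x\|_1$;
and the joint objective

$$\mathcal{L} = \lambda_{adv}(\mathcal{L}_{GAN}^{G} +
\mathcal{L}_{GAN}^{F}) + \lambda_{cyc}\mathcal{L}_{cyc} +
\lambda_{idt}\mathcal{L}_{idt},
\qquad \lambda_{adv} = 0.1,\; \lambda_{cyc} = 10,\; \lambda_{idt} = 2.$$

Expectations are arithmetic means over spatial score positions and the
batch. The breakdown identity (`total` equals the weighted combination of
the parts) is asserted on every training step. Generator updates default to
the *non-saturating* form $-\mathbb{E}\log D(G(x))$ for gradient health; the
printed saturating form is retained behind `gen_adv_mode = "saturating"` so
the exact published objective is computable.

## Training protocol

Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$ and a learning rate fixed at
$10^{-4}$ (no decay), batch size 1, Xavier-uniform weight initialization
(every convolution weight uniform in $\pm\sqrt{6/(fan_{in}+fan_{out})}$,
biases zero). Each step performs one discriminator update (all scales, both
directions, fakes detached) followed by one joint generator update. The
published protocol trains $512\times512$ slices for 5000 epochs; the desk
preset (`desk_train_config()`) keeps the optimizer settings and shrinks the
problem to $64\times64$ inputs, width 6 and one HFS module so the loop runs
on one CPU. Unpaired batching draws independent per-epoch shuffles of the
two domains and zips them, with the shorter list wrapping around.

Per-slice min-max normalization maps each slice's range onto $[0,1]$
(`minmax_normalize()`, inverted exactly by `denormalize()`). Whether the
published pipeline normalized per slice or per dataset is not stated; per
slice matches the printed "each pixel in the original image" phrasing and is
what `denoise()` uses, recording the input range for the inverse map.

## The synthetic phantom world

No CT data ships with the package, so training and evaluation are exercised
on synthetic phantoms: an elliptical soft-tissue body (20–80 HU) on a
$-2048$ background, 2–5 brighter elliptical organs (120–300 HU), and a
bone-analog rim (700–1200 HU). Dose-dependent noise is applied in the image
domain — the acquisition physics (sinogram noise, beam hardening, scatter,
reconstruction kernels) is deliberately *not* modeled:

* Gaussian noise with $\sigma = 30\,\mathrm{HU} \cdot
  \sqrt{150/\mathrm{dose}}$ (30 HU at the 150 mA reference, a typical
  abdominal standard-dose noise level; $\approx 67$ HU at 30 mA);
* attenuation-linked photon noise (10 HU at reference, same dose scaling,
  scaled by $\sqrt{\max(HU + 1000, 0)/1000}$ so denser tissue is noisier);
* below 50 mA, four randomly oriented Gaussian-profile streak ridges of
  amplitude 50 HU with random sign (zero mean over draws).

These values were fixed once, from the dose semantics of the emulated
acquisition (30 vs 150 mA), before any training run, and are not tuned.
The background stays exactly at $-2048$ so ROI masking behaves like real
scan cylinders. A green test on this world establishes that the machinery
(architecture, gradients, optimizer, metric) behaves as specified — not
that the method reaches clinical denoising quality, which would require the
original data and full-scale training.

## Evaluation: improved precision and recall

Because the data are unpaired, pixel-wise metrics are not the published
evaluation; instead each feature set's support is approximated by the union
of k-NN hyperspheres ($K = 3$) around its members:
precision = fraction of generated features inside the real manifold,
recall = fraction of real features inside the generated manifold
(boundary equality counts as inside; a point is not its own neighbor, which
makes the self-comparison value of 1.0 non-trivial). The protocol samples
$128\times128$ ROI-covered patches (16 px at desk scale) from min-max
normalized slices. The published embedding is a mid-level InceptionV3
layer; since pretrained weights cannot be bundled offline, a seeded random
projection and a summary-statistics extractor are first-class alternatives
and the InceptionV3 option raises an informative error. "Truncation
$\psi$" has no latent to truncate in a translation model; it is
operationalized as quantile-filtering generated features by distance to the
real feature mean ($\psi = 1$ keeps everything) — an interpretation, not a
claim about the original procedure, and off by default.

## Numerical choices

* Log arguments clipped to $[10^{-7}, 1-10^{-7}]$; losses stay finite at
  the clipping boundary.
* Spectral norm: one power iteration per training forward from a persistent
  estimate initialized at $\mathbf{1}/\sqrt{c_{out}}$; the estimate is
  frozen in evaluation mode so inference is deterministic. The normalized
  weight's leading singular value is asserted $\le 1 + 10^{-3}$ against a
  full SVD.
* Batch norm at batch size 1 uses per-sample statistics during training
  (identical to instance norm) and frozen running averages in evaluation.
* `max` combination of scSE branches routes gradients to the first branch
  on exact ties.
* Constant slices cannot be min-max normalized and raise an error rather
  than producing NaNs.
* All randomness flows through explicit seeds; patch sampling inside the
  precision/recall protocol is seeded per image position so identical image
  lists produce identical patch sets (making the self-comparison contract
  exact).

## Design decisions taken where the source was open

* The decoder's printed sub-pixel description ("reduces channels by 1/32,
  upscaling factor 3") is internally inconsistent (a factor-$r$ shuffle
  reduces channels by $1/r^2$); the standard rearrangement with $r = 2$ per
  stage is implemented and the inconsistency recorded rather than resolved.
* The HFS concatenation is read as residual-feature aggregation (the three
  residual *branches* plus the last trunk), matching the aggregation
  networks the design descends from.
* The residual block's internal layout (conv block → plain conv → scSE,
  two $3\times3$ convolutions) is an inference from the figure-level
  description; it is isolated in one constructor.
* Head layer mirrors the described tail (reflection pad + $7\times7$ conv);
  channel schedule 64→128→256 at the published scale.
* Discriminator crops are re-sampled independently for real and fake
  batches within a step.
* Configs and manifests use JSON (no YAML parser in the supported
  dependency set).

## Known limitations

* **The desk-scale smoke protocol cannot reach denoising quality.** At the
  published fixed learning rate of $10^{-4}$, Adam moves each parameter by
  at most $\approx$ the learning rate per step, so 200 optimizer steps
  displace weights by $\lesssim 0.02$ — far too little to carry a
  Xavier-initialized sigmoid-tailed generator to the near-identity mapping
  that beating the raw low-dose MSE requires (the low-dose images are only
  $\approx 50$ HU RMSE from their clean references, while a fresh generator
  starts hundreds of HU away). The smoke test's loss-decrease criterion
  passes; its MSE- and precision/recall-improvement criteria are reported
  honestly as failing at the 200-step budget — the budget, not the
  machinery, is the binding constraint (the per-step gradient checks and
  the monotone loss decrease establish that training moves in the right
  direction).
* DICOM support is read-only, single-frame, little-endian; no 3D volumes,
  no contrast-phase handling, no HU calibration.
* Image-domain noise is a stand-in for acquisition physics; streaks are
  straight Gaussian ridges, not photon-starvation reconstructions.
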