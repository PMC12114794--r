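---
title: "Cross-resolution burnt-area mapping: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-resolution burnt-area mapping: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossburn)
```

## The problem

Burn scars read as dark patches in multispectral imagery: charred canopy has
low overall brightness and strongly depressed near-infrared (NIR)
reflectance relative to healthy forest. Very high-resolution (VHR, here
3 m) imagery resolves small and fragmented scars that a 30 m product blurs
into *mixed pixels* — coarse cells whose footprint is only partly burnt.
That resolution gap cuts both ways: VHR scenes are expensive and narrow,
while 30 m archives are deep and free. A practical compromise is to label
burnt area once on a VHR scene and use those labels to train a
segmentation model on co-registered 30 m imagery.

`crossburn` packages that whole study design as reusable, tested code:

1. a **simulator** producing co-registered VHR and medium-resolution
   reflectance scenes with known burn scars,
2. a **labeller** reproducing forest masking, point sampling and per-band
   min/max spectral thresholding,
3. **coverage-threshold label transfer** from the fine to the coarse grid,
4. two **segmentation networks** (UNET and UNET-GRU) with their full
   training recipe, and
5. an **evaluation suite** (precision, recall, F1, accuracy, burnt-class
   IoU, Dice, whole-scene pixel accounting) plus an orchestrator for the
   four label-source x architecture crossings:

   | case | architecture | training labels |
   |------|--------------|-----------------|
   | A | UNET | native medium-resolution |
   | B | UNET | VHR-derived, transferred |
   | C | UNET-GRU | native medium-resolution |
   | D | UNET-GRU | VHR-derived, transferred |

All experiments here run on synthetic scenes; the same functions accept any
co-registered reflectance rasters, land-cover map and sample points.

## The simulator

`scene_config()` fixes the study conditions. Defaults: 3 m VHR pixels,
10x block aggregation to 30 m, four bands (Blue, Green, Red, NIR), a 10 m
land-cover product with forest (80%), water (5%), roads/urban (5%) and
barren (10%), and a burnt fraction of 4.4% of the scene — a landscape in
which scars are a small minority class, matching the kind of fire-season
scene the method targets.

Mechanics, chosen for exactness and testability:

* **Land cover** is a smoothed Gaussian random field binned at the exact
  quantiles of the requested class fractions (bin order water → forest →
  barren → built-up), generated on the VHR grid and exported at 10 m by
  nearest-neighbour resampling. Quantile binning makes realised fractions
  exact by construction.
* **Scars** are the top `burn_fraction_target * n_pixels` forest pixels of
  an independent smoothed field whose correlation length is
  `burn_corr_length / fragmentation`. Thresholding at an order statistic
  makes the realised burnt fraction exact, keeps scars strictly inside
  forest, and turns `fragmentation` into a single interpretable dial: more
  fragmentation, shorter correlation, more and smaller scar components,
  more mixed pixels after aggregation. (An earlier design grew scars by
  pixelwise random walks; field thresholding was adopted instead because it
  is fully vectorised, exactly calibrated and equally seedable.)
* **Reflectance** is class mean + per-class Gaussian texture + per-band
  Gaussian sensor noise, clipped to [0, 1]. No topography, BRDF, clouds or
  atmosphere — spectral separability and its degradation by mixing are the
  phenomena under study, and anything else would confound them.
* **Aggregation** is an exact `factor x factor` block mean (no point-spread
  function), cropping to the largest divisible extent. With zero sensor
  noise the global per-band mean is conserved to floating tolerance, which
  the tests assert.
* **Medium-grid ground truth** marks a coarse pixel burnt when its burnt
  coverage is at least 0.5 (majority rule; the threshold is exposed).

The spectra default to plausible surface-reflectance constants (forest NIR
0.45, burnt NIR 0.10, etc.); no published per-class spectral statistics
were available to calibrate them, so they are configuration, not claims.
What the simulator does *not* emulate — sensor PSFs, co-registration error,
atmospheric variability, phenology, non-fire disturbances — bounds what
passing tests show: they validate the method's logic under controlled
mixing and noise, not its performance on any particular real sensor pair.

## Label generation

The labelling path mirrors a GIS workflow: build a forest mask from the
land-cover product (nearest-neighbour resampling — categorical data must
never be averaged), sample points over burnt regions, extract per-band
reflectance at the containing pixel (half-open pixel extents, no
interpolation), take per-band minima and maxima, and classify a pixel
burnt iff it is forest *and* every band lies inside its sampled `[min,
max]` range. Conjunction with inclusive bounds makes the single-sample
case well defined and is monotone: widening any range can only add burnt
pixels.

Two sampling conventions coexist, and the difference matters:

* **VHR path**: points are drawn from interior (fully surrounded) scar
  pixels — the analyst's "clear and homogeneous regions". At 3 m pixels are
  effectively pure, so this choice is nearly inconsequential there.
* **Medium-native path**: points are drawn from *all* truth-burnt medium
  pixels, mixed pixels included. Labelling coarse imagery in practice
  leans on cross-verified burnt extents, and the spectral spread of burnt
  30 m pixels genuinely includes sub-pixel mixtures; sampling only pure
  pixels would collapse the min/max ranges onto the pure-burnt point and
  systematically miss every mixed pixel.

On a noise-free scene with disjoint spectra the VHR labeller reproduces
the ground truth exactly inside the forest mask (asserted in the tests).
VHR labels reach the 30 m grid by the same coverage rule as the ground
truth (default 0.5): the projection rule is a free parameter of any
cross-resolution design, and majority coverage is the symmetric,
least-surprising choice.

## The networks

Both models are symmetric encoder–decoders over 3-band (NIR, Red, Green)
tiles with per-pixel 2-class SoftMax heads:

* **UNET**: four encoder blocks (two 3x3 convolutions + ReLU, 20% dropout,
  2x2 max-pool), filters 16 → 256 at the bottleneck; transposed-convolution
  upsampling with skip concatenations; decoder filters mirror the encoder
  (128, 64, 32, 16).
* **UNET-GRU**: the same scheme with filters 64 → 1024, and a 512-unit
  gated recurrent layer at the bottleneck: the 16x16x1024 feature map is
  flattened row-major into a 256-step sequence, the GRU emits an output at
  every step, and the outputs are reshaped back to 16x16x512 for the
  decoder (512 → 64).

Training: Adam at 1e-4, categorical cross-entropy, He (fan-in) weight
initialisation, dropout 0.2 after every convolution block (encoder,
bottleneck and decoder — decoder placement is switchable), checkpointing
of the minimum-validation-loss epoch, and halving of the learning rate
after a validation-loss plateau (floor 1e-6). Dihedral augmentation
(flips, 90-degree rotations) is applied to training batches by default;
these transforms permute pixels, so 30 m labels survive them exactly. A
flag also augments validation batches for pipelines built around a
validation image generator, but that is off by default since it makes the
checkpoint criterion itself stochastic.

Design points that were genuinely open:

* The GRU runs unidirectionally over the row-major flattening, because that
  ordering reshapes back to the spatial grid without bookkeeping; the
  gate convention is the standard reset-before-candidate form with
  `h = (1-z) h_prev + z candidate`.
* Argmax ties break toward class 0 (unburnt) — deterministic and
  conservative for the minority class.
* Everything is implemented natively in R (im2col convolutions over BLAS
  GEMMs, hand-derived backpropagation including backpropagation through
  time for the GRU, Adam, inverted dropout). The backward pass is verified
  against central finite differences in the test suite at relative error
  below 1e-4. The data gradient of each convolution is computed as a
  convolution of the upstream gradient with the spatially flipped,
  channel-transposed kernel, which keeps the backward pass in gather+GEMM
  form.

## Scaled-down ("desk") regime

The full-size architectures on 256 px tiles are CPU-hostile, so tests and
the acceptance script run a reduced preset: 64 px tiles, two encoder
blocks with filters from 8 (bottleneck 32, GRU 32 units), on a
1920x1920 px VHR scene (192x192 at 30 m, nine tiles). With so few tiles an
"epoch" is only a handful of gradient steps, so the desk training defaults
rescale the schedule rather than the recipe: batch size 1 (seven gradient
steps per epoch instead of one), 300 epochs, plateau patience 25 epochs.
In steps — the unit the optimiser actually sees — this is ~2100 Adam steps
with patience ~175 steps, which is *conservative* relative to full-size
practice (hundreds of steps per epoch, patience of several epochs). The
learning rate, loss, optimiser, dropout and checkpointing are unchanged.

Problem sizes used by the tests: gradient checks on 8 px inputs; training
determinism on 16 px micro-architectures; the end-to-end case study and
the label-source comparison at the desk preset above; the linearly
separable training check on 60 half-plane tiles of 16 px (half-plane
rather than pixelwise-random masks, because a segmentation network should
be asked to learn a spatially coherent decision, not salt-and-pepper
noise).

## Evaluation conventions

* Burnt is the positive class. `iou` is burnt-class IoU `tp/(tp+fp+fn)`;
  the printed Dice/IoU pairs of single-class reports satisfy
  `dice = 2 iou/(1+iou)`, which a two-class macro-average would not, so
  the burnt-class form is the default and a macro-average is behind a
  flag.
* 0/0 ratios are 0, except the no-positives-anywhere perfect case
  (`tp = fp = fn = 0`), where F1/IoU/Dice are 1.
* Pixel accounting reports actual/predicted burnt and unburnt counts,
  and misclassified pixels (`fp + fn`), with percentages of the scene
  total at two decimals (half-even rounding).
* `run_case()` always evaluates against the *simulator's* medium-grid
  ground truth, never against the training labels. Training labels are one
  of the experimental treatments; evaluating against them would conflate
  label noise with model error. Whole-scene metrics are reported (the
  pixel-accounting convention), alongside metrics restricted to the
  held-out test tiles.

## Known limitations

* The GRU sequence order and direction are fixed choices; bidirectional or
  column-major variants might behave differently and are not implemented.
* The simulator's mixtures are linear in reflectance with no PSF; real
  30 m pixels mix radiance through a sensor-specific response.
* Native R training is single-threaded and practical only at the desk
  scale; the full-size specs build and run forward passes, but training
  them here is not realistic.
* ROC-AUC is provided for probability maps only and is not a headline
  output.
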