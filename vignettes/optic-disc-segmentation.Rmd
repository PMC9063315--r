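---
title: "Attention-enhanced optic-disc segmentation: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-enhanced optic-disc segmentation: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Locating the optic disc (OD) in fundus photographs of premature infants is a
small-target, low-contrast segmentation problem: the disc covers a few
percent of the image, its boundary is often diffuse, and neonatal images
suffer from uneven illumination. `odseg` implements a U-shaped
encoder--decoder network for this task together with the two attention
modules that distinguish it from a plain residual U-shape, a joint
Dice + binary-cross-entropy objective, pixel-level evaluation metrics, and a
synthetic data generator so that the whole pipeline can be exercised and
tested without clinical data.

The encoder is a ResNet34 trunk with the classifier head removed. Five
feature taps are used: the stem convolution output (64 channels at 1/2
resolution) and the four residual stages (64, 128, 256, 512 channels at
1/4 ... 1/32 resolution). Three components are assembled around it:

* **DsSE (dual-scale semantic enhancement)** reconstructs each of the three
  inner skip connections. For a skip map $F \in \mathbb{R}^{C\times H\times W}$
  and its next-deeper neighbour $N \in \mathbb{R}^{2C\times H/2\times W/2}$,
  $N$ is mapped to $C$ channels by a $1\times1$ convolution and bilinearly
  upsampled; $1\times1$ convolutions then form a query from the upsampled
  map and a key/value pair from $F$, with query/key width $\max(\lfloor C/r
  \rfloor, 1)$ for compression ratio $r = 16$. The similarity matrix
  $E = \mathrm{softmax}(QK)$ is row-normalised over key positions, so each
  query position carries a convex combination of all $H\cdot W$ value
  vectors; the re-shaped response $T$ is added residually, $M = F + T$.
* **AM (attention module)** is a squeeze-style gate: $1\times1$ convolution
  down to $\max(\lfloor C/r\rfloor,1)$ channels, ReLU, $1\times1$ back to
  $C$, sigmoid. Its confidence map $P \in (0,1)^{C\times H\times W}$
  multiplies the input, $Y = P \odot X$.
* **MsFF (multiscale feature fusion)** sits on top of the encoder. Stage-3
  and stage-4 maps are max-pooled (factors 4 and 2) to stage-5 resolution,
  each of the three maps passes its own AM at native width, the shallow
  gated maps are projected to the stage-5 width by biased $1\times1$
  convolutions, and the fusion is
  $Y_F = X_5 + Y_5 + (1 - P_5)\odot(Y_3' + Y_4')$: wherever the deepest
  map's confidence is low, detail from the shallower stages is re-injected.

The decoder uses four blocks (1x1 reduce by a factor of 4, 3x3 transposed
convolution doubling resolution, 1x1 to the skip width; each convolution
followed by batch normalisation and ReLU), skip fusion by element-wise
addition, and a head (3x3 transposed convolution to 32 channels, two 1x1
convolutions) that restores full resolution and emits one logit per pixel.
Probabilities are thresholded at 0.5 with ties mapped to foreground.

The training objective is
$L_\mathrm{total} = L_\mathrm{Dice} + L_\mathrm{BCE}$ with
$L_\mathrm{Dice} = 1 - \frac{2\sum XY + \varepsilon}{\sum X + \sum Y +
\varepsilon}$; the Dice term optimises overlap at the image level while the
cross-entropy supervises individual pixels, the usual combination when the
foreground is rare.

## Architectural choices that were genuinely open

Several wiring details are not derivable from the variant descriptions
alone; they were fixed once, by parameter-count calibration against the
published totals of the four variants (21.66 / 21.93 / 21.91 / 22.18 M),
and are verified by the acceptance suite:

* **DsSE placement.** Three instances, on the skips at 64, 128 and 256
  channels, each consuming the next-deeper stage. Exactly this set costs
  ~0.27 M parameters, matching the printed delta; adding an instance on the
  deepest stage would overshoot it (that stage is instead handled by MsFF).
* **Skip fusion by addition, not concatenation.** Concatenation would
  double decoder input widths and cannot reach the printed baseline total;
  addition also matches the residual style of the trunk.
* **MsFF channel harmonisation.** The AM gates run at each stage's native
  width and the gated maps are then projected to 512 channels. Projecting
  before the gates would cost ~0.33 M instead of the printed ~0.25 M.
* **MsFF downsampling** is max pooling (parameter-free, keeps the printed
  module cost attainable).
* **Head widths** 64 -> 32 -> 32 -> 1: the smallest natural reading of "a
  3x3 deconvolution and two 1x1 convolutions", contributing ~0.02 M; the
  1 % tolerance on totals absorbs this convention.
* **Softmax orientation.** Row-wise (over key positions), the standard
  non-local-attention convention; it is what makes the weighted sum a
  convex combination, and it is pinned by the brute-force oracle tests.
* Attention-branch convolutions carry biases and no normalisation layers;
  trunk convolutions are bias-free (their batch norm absorbs the shift).

Two departures from strict minimalism are deliberate: the compressed
attention width is clamped to at least one channel so narrow test models
remain valid (clamping is reported once, via a message), and the final
logit convolution's bias starts at -3, the logit of a ~5 % foreground
prior. Starting at the class prior is standard practice for rare-foreground
segmentation; without it the first epochs are spent driving predictions
toward background before the disc is discovered.

## Optimisation protocol

Defaults mirror the published protocol: Adam (learning rate 5e-4, weight
decay 1e-4, batch size 16, 100 epochs), constant learning rate (only the
initial rate is specified; no schedule is invented), online augmentation of
the training split only, and model selection by the best validation Dice
computed at threshold 0.5 on un-augmented images. Augmentation applies,
each with probability 0.5 (the probability is a package convention),
horizontal flips, rotations uniform in [-10, 10] degrees, and small affine
perturbations (scale 0.9--1.1, translation <= 5 % per axis, shear <= 5
degrees), with identical geometry for the image (bilinear) and the mask
(nearest neighbour, so it stays binary).

Pretrained ImageNet encoder weights are supported only via a user-supplied
checkpoint (`pretrained_encoder = TRUE` plus `encoder_weights`); none ship
with the package, and all reported runs start from He initialisation.
Parameter counts are initialisation-independent.

The **desk profile** (`desk_profile()`) is a named reduced configuration so
that full-protocol and reduced runs cannot be confused: width multiplier
0.25, 128x128 inputs, 20 epochs, batch size 8, learning rate 2e-3. The
larger step size reflects the short optimisation budget (160 updates) and
the narrow model; 5e-4 also converges, just not within 20 epochs.

## The synthetic generator: what it emulates and what it does not

`generate_sample()` renders 640x480 scenes: a reddish-orange background
with a smooth linear illumination gradient and radial vignette; a bright
ellipse (semi-axes 25--60 px, anywhere fully inside the canvas with a 5 px
margin) whose *image* boundary is Gaussian-blurred while the *mask* stays
the exact ellipse interior; dark vessel-like random-walk curves emanating
from the disc centre; additive Gaussian noise (sd 0.02); bilinear resize to
256x256 and [0,1] normalisation. Two difficulty tiers mimic the clinically
observed split between obvious discs (contrast 0.7--1.0, blur sigma 1--3 px)
and blurred discs (contrast 0.15--0.3, sigma 3--6 px). The geometry keeps
the foreground fraction inside 0.3--6 % of pixels, the small-target regime
the joint loss exists for.

These are generator conventions, not statistics fitted to any clinical
dataset. Real neonatal fundus images carry pathology, specular artefacts,
motion blur and annotation ambiguity that the generator does not attempt;
consequently, passing tests demonstrate that the architecture, losses and
training loop work as specified, not that clinical accuracy figures
transfer. The published headline Dice/sensitivity on the in-house cohort is
deliberately out of reach here and is not asserted anywhere.

## Numerical conventions and degenerate inputs

* Dice smoothing $\varepsilon = 1$ by default (finite loss and gradient on
  empty masks); tests evaluate identities in the analytic
  $\varepsilon \to 0$ limit. Probabilities are clipped to
  $[10^{-7}, 1-10^{-7}]$ before logarithms. The cross-entropy is reported
  as a per-pixel mean so magnitudes are resolution-independent (`reduction
  = "sum"` recovers the raw pixel sum).
* Dice from confusion counts uses the standard $2TP/(2TP+FP+FN)$ form.
  Empty-against-empty masks score 1 by convention; sensitivity is undefined
  (NA, excluded from aggregation) when the ground truth is empty; both
  conventions are announced via messages.
* The paired t-test returns p = 1 for identically zero differences and
  p = 0 for a zero-variance non-zero shift.
* Softmax rows are max-shifted before exponentiation; batch normalisation
  uses biased batch variance with momentum-0.1 running statistics
  (evaluation mode uses the running values).
* Resizing uses half-pixel-centre sampling with border clamping (bilinear
  for images, nearest for masks); the transposed convolutions are exact
  2x adjoints of stride-2 convolutions, so output sizes double exactly and
  inputs must be divisible by 32.
* Binarisation ties (probability exactly 0.5) map to foreground,
  everywhere.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent oracle
written without the package's machinery: per-pixel loop transcriptions of
both attention modules and the losses, closed-form parameter arithmetic,
and central finite differences through the entire network (the backward
pass of every layer, both attention modules and the loss agrees with
finite differences to ~1e-6 relative error; the probe step must be small
because ReLU and max-pool make the loss only piecewise smooth). Training
and evaluation tests run at reduced scale -- 0.125-width models on 64x64
inputs for structural checks, the 0.25-width desk profile on 64 synthetic
images for the convergence check, 1000 replicates for the t-test
calibration -- sizes chosen so the whole suite stays comfortably
interactive while still exercising every code path at full depth.

## Known limitations

* CPU-only, double precision, single-process: the full 256x256 protocol at
  width 1 is buildable and runs forward passes, but full-protocol training
  at that scale is impractical in this engine; the desk profile is the
  supported training scale.
* No learning-rate schedule, no early stopping, no test-time augmentation,
  no multi-head attention -- none of these appear in the target design.
* The generator produces one disc per image and no lesions; domain gaps to
  clinical data are expected and documented above.
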