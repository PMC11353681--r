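---
title: "Quanvolutional neural networks for ultrasound lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quanvolutional neural networks for ultrasound lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quanvnet)
```

## The model

`quanvnet` implements a hybrid quantum–classical classifier for small
grayscale images, aimed at binary breast-ultrasound lesion discrimination
(benign/normal vs malignant). The feature extractor is *quanvolutional*: a
parameterized 9-qubit circuit plays the role of a 3×3 convolutional kernel.
For every 3×3 window of the image,

1. **Angle embedding.** Each pixel value $p \in [0,1]$ is written into one
   qubit by a rotation $R_x(p \cdot \pi/2)$, so the nine pixels of a window
   (row-major) become the rotation angles of nine qubits. Pixel 0 leaves the
   qubit in $|0\rangle$ ($\langle Z\rangle = 1$); pixel 1 rotates to the
   equator ($\langle Z\rangle = 0$).
2. **Entangled kernel.** The register passes through a strongly entangling
   circuit built from one SU(4)-style two-qubit block per adjacent wire pair
   $(0,1),(1,2),\dots,(7,8)$: a U3 on each qubit, three CNOTs interleaved
   with $R_z$/$R_y$ rotations, and a closing U3 on each qubit — 80 gates in
   total. All eight blocks **share** the same 15 angles, so one kernel
   exposes exactly 15 trainable parameters, the quantum analogue of
   convolutional weight sharing.
3. **Measurement.** The Pauli-Z expectation of each wire,
   $\langle\psi|Z_w|\psi\rangle \in [-1,1]$, yields the nine channel values
   of one output pixel.

Sliding this kernel with stride 2 and no padding turns a 14×14 image into a
6×6×9 feature map. The map is rescaled by $v \mapsto (v+1)/2$ so that a
second 15-parameter kernel can re-embed it. Two compositions of the second
layer are provided:

* `spatial` (default): each of the nine channels is treated as its own 6×6
  image and quanvolved again, giving 2×2×9 per channel, concatenated to
  2×2×81. This reading gives two genuine convolutional layers.
* `stacked`: the nine channel values at each spatial cell are re-encoded as
  one 3×3 patch, keeping the 6×6×9 geometry.

Both flatten (row-major, channels fastest) to 324 features feeding a single
dense unit. The raw score is a logit; the loss is binary cross-entropy *with
logits* (the numerically stable form $\max(z,0) - zy + \log(1+e^{-|z|})$),
and prediction applies a sigmoid threshold of 0.5, with a tie classified as
malignant because the positive call requires *strictly* greater than the
threshold. The trainable budget is 30 quantum angles + 325 dense parameters
= 355 (`param_count()`).

## Simulation and gradients

The circuits are simulated exactly: the full complex statevector (512
amplitudes for 9 qubits) is propagated gate by gate in compiled code, with
qubit 0 as the most significant bit of the basis index. There is no shot
noise, no noise model and no mixed states; global phase is not normalized
away, which is benign because every observable used is phase-invariant.
Unitarity of each gate holds to 1e-12 and circuit application preserves the
norm to 1e-10; a dense Kronecker-product oracle in the test-suite verifies
gate-wise application against explicit 512×512 matrix products.

Two independent differentiation routes are implemented:

* **Parameter-shift rule** (`grad_param_shift()`): each angle position
  contributes $[f(\theta + \pi/2) - f(\theta - \pi/2)]/2$; slots feeding
  several positions (the shared kernel angles feed eight each) accumulate
  their contributions. This is the rule hardware would use.
* **Adjoint backpropagation** through the simulator: a reverse sweep that
  undoes gates while carrying the observable-weighted costate, giving the
  gradient of a scalar loss with respect to every circuit angle — including
  the encoding angles, which is how the loss gradient flows from the second
  quanvolution layer back into the first.

The training loop uses the adjoint route (one backward sweep costs about
three forward passes, against 30 shifted circuit pairs for parameter-shift);
the tests require the two routes and central finite differences to agree to
1e-6 on the kernel circuit, and the end-to-end model gradient to match
finite differences to 1e-5.

## Training protocol

Training follows the study protocol: Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8) with learning rate 1e-2, weight decay 1e-5, batch size 10, and
15 epochs on the real-data configuration. Weight decay is applied as an L2
term added to every gradient — quantum angles included — mirroring how a
global optimizer `weight_decay` setting behaves. Initialization draws
quantum angles from Uniform[0, 2π) and dense weights from
Uniform[−1/√324, 1/√324]; initialization, batch shuffling and the synthetic
generator all derive from one integer seed, so a run is bitwise
reproducible. Epoch metrics are loss and accuracy over the *full* training
and validation sets at epoch end, not running batch averages. The per-epoch
record is returned as a data frame and written by the CLI as one JSON line
per epoch.

The classical baseline mirrors the architecture: two 3×3 stride-2
convolutions with nine channels each — the second grouped channel-wise,
matching the per-channel second quanvolution — with biases and tanh
activations (tanh mirrors the $[-1,1]$ range of the expectation values; the
equivalence is an architectural judgment, since "same number of layers"
leaves the activation open), then the same dense head (217 parameters in
total).

## Data pipeline

The real-data path reads a MedMNIST-layout `.npz` archive (six arrays;
BreastMNIST ships 546/78/156 images at 28×28 under a 7:1:2 split). Pixels
are scaled to $[0,1]$ and the three clinical classes are binarized:
normal/benign form the positive class 1, malignant the negative class 0.
The archive's malignant label code is configurable (`malignant_code`,
default 0, the BreastMNIST convention). Preprocessing follows the study
recipe: 28→14 downsizing, normalization to $[0,1]$, and a nearly balanced
training subset. Concrete choices where the recipe names only the goal:

* **Downsampling** is non-overlapping 2×2 mean pooling — deterministic,
  library-independent, and exactly area-preserving — rather than
  interpolation.
* **Normalization** is global (per-dataset) min–max; a constant image maps
  to zero.
* **Balanced subset** keeps every minority-class image plus an equal-count
  seeded sample of the majority class ("nearly balanced" leaves the exact
  counts open; this rule is our convention).

## The synthetic generator

So that everything builds, trains and tests without downloads, the package
generates a synthetic stand-in for low-resolution breast ultrasound: a
mid-gray echo background (0.60) under multiplicative squared-Rayleigh
(exponential) speckle, smoothed by two passes of a 3×3 box filter to give
correlated grains, containing one hypoechoic (dark, 0.08) lesion per image. The two
phenotypes differ only in their margins:

* class 1 (benign): a filled ellipse with a heavily blurred margin (soft
  sigmoid edge, 3 px at the native 28×28 resolution);
* class 0 (malignant): the same ellipse family modulated by angular
  spicules, $r(\phi) = r_0(\phi)\,(1 + \texttt{irregularity}\cdot
  \sin(k\phi + \phi_0))$ with $k \in \{4,5,6\}$ lobes, and a sharp margin
  (0.3 px).

At `irregularity = 0` both generators collapse to the same ellipse family.
Defaults: `irregularity = 0.4`, `speckle_scale = 0.4`, 28×28 images,
balanced classes. Lesion size and position are standardized the way a
physical phantom would be (semi-axis 23–27% of the image side, aspect ratio
0.82–1, centre jitter ±1 px): during development we found that with wide
size/position jitter the class signal — which lives entirely in the margins
— did not survive 2× pooling to the 14×14 working resolution, leaving a
task that even a linear probe on image principal components could not
separate. The rendering (lobe counts, margin widths, contrast, nuisance
ranges) was therefore calibrated so that the classes are separable *at the
working resolution*, which is the generator's contract: a logistic
regression on two mask features (area, radial roughness = sd/mean of
boundary-pixel radii) exceeds 90% accuracy, and spiculated masks are
rougher than smooth ones by construction. The generator also returns the
ground-truth masks (attribute `"masks"`) so these checks are computable.

What the generator does **not** emulate: acoustic shadowing and posterior
enhancement, heterogeneous internal echotexture, multiple or absent
lesions, probe-dependent artefacts, and the class-imbalance and label noise
of clinical data. Passing tests on the synthetic task therefore demonstrate
that the pipeline can extract and learn margin-morphology signal at this
resolution — not that the model reaches any particular clinical accuracy.

## Numerical choices and degenerate inputs

* Complex double precision throughout; state norm validated to 1e-8 on
  construction, preserved to 1e-10 through circuits.
* CNOT lists the control wire first; the kernel's middle CNOT reverses
  direction relative to its neighbours, following the SU(4) block structure.
* A pixel value exactly 0 or 1 is valid (angles 0 and π/2); values outside
  $[0,1]$ are rejected rather than clipped.
* Images smaller than the 3×3 kernel, odd dimensions fed to the 2× pooler,
  empty splits, single-class subsets and non-binary labels all raise
  immediate errors.
* Zero-denominator precision/FPR values are reported as 0 with a
  `zero_denominator` flag rather than NaN.
* Display rounding (2 decimals) is half-away-from-zero; all stored values
  keep full precision.
* The one-vs-rest false-positive rate is FPR$_k$ = FP$_k/(n - $support$_k)$.
  Published per-class FPR pairs for this task sometimes follow other,
  undocumented conventions; this package deliberately implements only the
  standard definition.

## Problem sizes

The default working configuration is deliberately small — 14×14 inputs,
6×6×9 then 2×2×81 feature maps, 80-image training runs of 10 epochs for the
synthetic demonstrations — keeping a full training run in the low minutes
on one CPU while exercising every code path at the architecture's true
width (9 qubits, 512 amplitudes). The same functions run the full
BreastMNIST protocol (546 training images, 15 epochs) unchanged when an
archive is supplied.

A caveat on the scaled-down training demonstrations: with only 80 Adam
steps (80 images, batch 10, 10 epochs) at learning rate 1e-2, the training
trajectory is noisy — epoch accuracy can swing by tens of points between
epochs, and the peak reached within 10 epochs varies with the
initialization and shuffling seed. This mirrors the behaviour of the same
optimizer settings in any tensor framework at these problem sizes; the
packaged checks therefore report the peak epoch accuracy of a fixed-seed
run.

## Known limitations

* Exact statevector simulation scales as $2^n$; the register is capped at
  12 qubits, which covers the 3×3 kernel (9 qubits) comfortably but not
  larger kernels.
* The second-layer composition the original architecture intended is
  ambiguous ("the output is fed into another variational circuit"); both
  defensible readings are implemented (`spatial`, `stacked`) and neither is
  asserted as *the* original. They share the 324-feature head by
  construction.
* No multi-class head, no ROC sweeps, no learning-rate schedules, no early
  stopping, no data augmentation, no hardware backends, no shot noise.
* The CLI reads PNG directories and `.npz` archives; it does not download
  datasets.
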