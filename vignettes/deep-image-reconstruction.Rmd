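---
title: "Deep image reconstruction: model, assumptions, and desk-scale design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep image reconstruction: model, assumptions, and desk-scale design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeprecon)
```

## The problem and the model

Visual content — what a person is seeing, or imagining — is encoded across a
hierarchy of cortical areas. A convolutional network trained on object
recognition develops a feature hierarchy homologous enough to this cortical
hierarchy that a *linear* map from fMRI voxel activity to the network's unit
activations is a workable model of the measurement. `deeprecon` implements
the full decode-and-invert program built on that observation:

1. **Feature decoding.** For every scalar unit $\phi_i^{(l)}$ of every layer
   $l$ of a feature extractor, train a sparse linear readout from voxel
   activity $x$: $\hat y_i^{(l)} = w \cdot x + b$. Sparsity comes from an
   automatic relevance determination (ARD) prior; voxels are pre-screened by
   training correlation (at most 500 per unit).
2. **Reconstruction.** Find the image whose features match the decoded
   vector across layers:
   $$v^* = \arg\min_v \tfrac12 \sum_{l \in L} \beta_l
     \lVert \Phi^{(l)}(v) - y^{(l)} \rVert_2^2, \qquad
     \beta_l = 1 / \lVert y^{(l)} \rVert_2^2,$$
   minimized over pixels with L-BFGS (or momentum gradient descent), using
   the exact gradient backpropagated through the extractor. The
   $\beta_l$ weighting puts every layer's term on a comparable initial
   scale.
3. **Natural-image prior (optional).** Optimize instead over the latent
   code $z$ of a generator network $G$, $v^* = G(z^*)$, starting from the
   zero vector and clipping each element of $z$ to its allowed range after
   every step. Constraining the search to the generator's output manifold
   regularizes reconstructions toward its training distribution.
4. **Evaluation.** Pairwise identification: a reconstruction is compared
   with its own original and each other original of the same stimulus set
   (pixel-wise Pearson correlation as the judge); chance is 50%. Layer
   combinations are compared by round-robin winning percentages.

The key modeling assumptions are (a) a linear voxel-to-feature readout is
adequate, (b) pre-rectification unit outputs are the right decoding target,
and (c) feature-matching loss is a usable proxy for perceptual similarity.
The synthetic stack below makes (a) true *by construction*, which is
exactly what makes the pipeline testable: failures then indicate defects in
the estimator or optimizer, not model misfit.

## The feature extractor

The reference architecture is the 19-layer network (sixteen 3×3
convolutions in five blocks of 64/128/256/512/512 filters, each block
followed by 2×2 pooling, then 4096-4096-1000 fully connected layers) on
224×224 RGB inputs. The package carries it as a shape-level description:
`unit_counts(reference_extractor())` derives every layer's unit count by
shape propagation (e.g. conv1_1: $224 \cdot 224 \cdot 64 = 3{,}211{,}264$),
and the layer groups DNN1–DNN8 (five conv blocks, three fc layers) drive
layer-combination bookkeeping. Pre-trained weights are deliberately not
bundled; all computation with weights runs on **toy extractors** — seeded,
He-initialized networks of the same structural family
(`toy_architecture()`: two conv blocks and two fc layers on a 16×16×3 input
by default). Unit outputs are taken *before* rectification, flattened in a
fixed row-major (height, width, channel-last) order so serialized features
are portable; the channel-fastest order also makes a conv layer's filter
grouping a simple modulus.

Two variant details matter:

* **Imagery variant** (`make_imagery_variant()`): max pooling becomes
  average pooling and the rectifier becomes leaky (slope 0.2), keeping all
  weights and shapes. Average pooling and a leaky rectifier leave gradients
  defined everywhere, which suits reconstruction from the weaker, noisier
  imagery-derived features. The package exposes the variant as an explicit
  transformation and takes no position on whether imagery *decoders* should
  also be trained on variant features — both are possible via the same API.
* **Gradients** are exact analytic backpropagation (im2col convolution
  transpose, argmax routing through max pooling with lowest-index
  tie-breaking, rectifier masks), verified against central finite
  differences to 1e-4 relative error in the tests.

Input images are resized bilinearly to the extractor's input size; toy
extractors consume raw `[0, 255]` pixels with no mean subtraction (with
random weights there is no pre-training convention to honor).

## Preprocessing: from runs to samples

`preprocess_run()` fixes the order: nuisance regression → rest
normalization → despiking → block averaging.

* **Nuisance regression** removes, per voxel, the least-squares fit of an
  intercept, a linear trend, and six motion parameters. By default the
  voxel's mean amplitude is retained (`keep_mean = TRUE`): a full residual
  would have mean zero in every voxel, leaving the next step without a
  positive baseline to divide by. `keep_mean = FALSE` gives the fully
  orthogonal residual when that is what an analysis needs.
* **Rest normalization** expresses each voxel as percent signal change
  against its mean over the initial 24-s rest prefix, erroring on
  non-positive baselines (a ratio-only mode is available by flag).
* **Despiking** clips values beyond mean ± 3 SD (per voxel, within run) to
  the boundary. "Reduce extreme values" admits several readings; clipping
  is deterministic, idempotent, and preserves sample count, and the SD is
  computed once on the input so the boundary does not creep. We despike
  *after* normalization (the alternative order is a one-line change the
  API permits by composing the steps manually).
* **Block averaging** averages the volumes covering each stimulus block
  after shifting by 4 s — rounded to whole volumes (two at TR 2) — to
  compensate for hemodynamic delay: an 8-s block averages 4 volumes, 12-s
  averages 6, a 16-s imagery block 8.

Discarding pre-run scanner-instability volumes is the caller's concern; the
simulator never produces them.

## ARD feature decoding

`fit_ard()` implements Bayesian linear regression with a per-weight
Gaussian prior whose precisions $\alpha_i$ are optimized by fixed-point
evidence updates ($\gamma_i = 1 - \alpha_i \Sigma_{ii}$,
$\alpha_i \leftarrow \gamma_i / \mu_i^2$, noise precision
$\leftarrow (n - \sum_i \gamma_i)/\text{RSS}$). Columns are standardized
internally; weights with $\alpha_i > 10^8$ are pruned to exactly zero and
leave the active set, which keeps late iterations cheap and makes sparsity
literal rather than approximate. Convergence is declared when the largest
weight change drops below `tol` (1e-4 by default); hitting the iteration
cap returns the current fit with `converged = FALSE` rather than failing.
These algorithmic constants are the package's own choices — the estimator
family, not specific constants, is the contract — and all are exposed as
arguments.

Voxel screening (`select_voxels()`) ranks by **absolute** correlation:
a strongly anticorrelated voxel carries as much linear signal as a
correlated one, and the regression sign-corrects downstream. A signed mode
exists for comparability. Ties break toward the lower voxel index so runs
are bit-reproducible.

Decoded test features are trial-averaged (rows sharing a stimulus label are
averaged before prediction) and then **norm-corrected**: each layer's
decoded vector is rescaled by one scalar so its norm matches the mean true
feature norm over a reference image set. Trial averaging shrinks noise and
with it the decoded vector's norm; norm correction undoes that systematic
shrinkage without touching direction. At desk scale the reference set is
100 seeded synthetic images (the full-scale protocol uses 10,000 natural
images); when only a unit subsample is decoded, reference norms are
computed over the same subsample.

Accuracy is reported per unit (correlation across samples) or per sample
(correlation across units, after z-normalizing both decoded and true
values with per-unit training statistics — otherwise baseline and scale
differences across units fabricate correlation). Constant series have no
defined correlation and are reported missing, excluded from averages.
`abs_feature_comparison()` reproduces the raw-versus-absolute analysis:
decoders are trained on raw and on absolute targets, unit accuracies are
averaged within each convolution filter, and the table is sorted ascending
by raw accuracy.

## Reconstruction: numerical choices

* **Optimizers.** L-BFGS (history 10) via the standard box-constrained
  implementation, or momentum gradient descent (momentum 0.9, step 1.0 on
  the normalized gradient, 200 steps by default). Normalized-gradient steps
  are robust to the loss scale but converge only to within the step size;
  `normalize_gradient = FALSE` with a curvature-appropriate step gives
  asymptotically exact convergence, which the closed-form oracle tests use.
* **Best-iterate tracking.** The returned image is the best-loss iterate
  encountered, so the final loss can never exceed the initial loss even if
  a line search ends on an uphill probe. Snapshots (optional) record the
  best-so-far image at a fixed evaluation cadence, giving a strictly
  decreasing loss sequence until the convergence plateau — the
  "optimization process" view.
* **Initial image.** Presets: spatially uniform at a configurable mean RGB
  (the main-analysis choice; at desk scale mid-gray 128), the zero image,
  or a seeded uniform-random image.
* **Pixel range.** Pixels are unconstrained during optimization and clipped
  to `[0, 255]` only on export (`clip_image()`/`write_image_png()`).
  Clipping inside L-BFGS would silently violate its line-search
  assumptions; an interior constraint also has no basis in the model.
* **Latent reconstruction.** Starts at $z = 0$; with momentum descent each
  element is clipped to its range after every step, with L-BFGS the range
  enters as native box constraints. Latent bounds default to ±3 per
  element (a unit-Gaussian latent's practical range; the identity
  generator, whose latent is on the pixel scale, defaults to ±255). The
  exact range used with a pre-trained generator belongs to that
  generator's own training convention and is configurable.
* **Divergence** (a non-finite loss) raises an error carrying the loss
  trace rather than returning a poisoned result.

One property worth stating precisely: for a zero-offset linear extractor,
scaling all decoded vectors by $c$ and recomputing $\beta_l$ scales the
minimizer by exactly $c$ — the reconstruction is unchanged *up to intensity
scale*, and the Pearson-based evaluation is invariant to that scale. The
weights absorb the global SNR ambiguity of decoded features in exactly the
sense that matters for identification.

## Evaluation protocol

`pairwise_identification()` compares each reconstruction with every
(own-original, other-original) pair — $n-1$ comparisons per reconstruction,
$n(n-1)$ in total, e.g. 2,450 for 50 test images. A trial is correct when
the reconstruction correlates strictly higher with its own original; exact
ties count 0.5 (unbiased under the null, and deterministic).
Comparison-weighted and image-weighted pooled accuracies are both reported;
they coincide at equal per-image comparison counts. Human raters are out of
reach of software, so the correlation judge stands in for them; the
`similarity` argument is the hook for any alternative perceptual metric.
`winning_percentage()` runs the round-robin between reconstruction
conditions (8 layer combinations → 28 pairs); with no ties the grand mean
is exactly 50%, a conservation property the tests assert.

## What the synthetic stack emulates — and what it does not

* **Stimuli.** Colored shapes: 5 parametric glyphs (square, plus, tee, ell,
  diamond) × 8 colors, with the six chromatic colors matched in Rec. 709
  relative luminance to full-intensity blue (the dimmest pure hue, hence
  the shared ceiling; the matching method itself is a package choice).
  Letters: the ten glyphs A, C, E, I, N, O, R, S, T, U from a bundled 5×7
  bitmap font, black on white. Natural-like textures: seeded low-frequency
  gratings plus Gaussian blobs — the spatial-frequency falloff of
  photographs with no objects, no semantics, and no copyright.
* **Encoding.** Voxels respond as a sparse linear combination of true layer
  features plus i.i.d. Gaussian noise ($x = Wf + \varepsilon$), noise drawn
  independently per presentation. This realizes the decoder's linearity
  assumption exactly.
* **Runs.** A 24-s rest prefix, boxcar block responses delayed by the
  hemodynamic shift and scaled to percent signal change around baseline
  100, linear drift, motion given as respiration-band oscillation
  (0.15–0.35 Hz) plus scan-to-scan jitter coupled into voxels through a
  random matrix, and white noise. The oscillation-plus-jitter motion model
  reflects a head-restrained subject; an unbounded low-frequency walk would
  instead overlap the block design's own spectrum, and nuisance regression
  would then remove genuine signal no matter how small the motion — a
  property of the regression, not of the pipeline under test.

Not emulated: hemodynamic response shape beyond boxcar-plus-shift,
retinotopic spatial structure across voxels, physiological noise
correlations, session effects. Passing tests therefore demonstrate that
the estimators and optimizers do their jobs under the model's own
assumptions — not that the model fits real scanner data.

## Desk-scale study conditions

The default end-to-end experiment (`end_to_end_experiment()`) uses 220
training and 40 test stimuli at 12×12 pixels, a 500-unit seeded subsample
of conv1_1 (1,152 units), 500 voxels with 12 encoded units each, 3 test
repeats, ARD on the top 100 voxels with 30 update sweeps, and 200 L-BFGS
iterations per reconstruction; encoding noise is swept over
{0.1, 1, 5, 25} × the clean response SD. These sizes were chosen once so
the experiment represents a plausible single-session protocol at toy
resolution; high SNR (0.1) is expected to give near-ceiling identification,
and 25× drives decoded features toward the training-mean prediction, whose
identification accuracy is chance by symmetry. The orchestrated
`run_pipeline()` additionally pushes every sample through run synthesis and
the four-step preprocessing at 2% signal amplitude, 44 blocks per run.

## Known limitations

* The reference network runs only if externally supplied weights are
  attached; everything quantitative in the package's own tests uses toy
  extractors.
* ARD fixed-point updates maximize evidence locally; with heavily
  correlated voxel columns the selected support can differ from the
  ground-truth support while predicting equally well (the tests therefore
  measure weight mass and prediction, not support identity).
* Momentum descent with normalized gradients stalls at step-size scale by
  design; use L-BFGS (or un-normalized steps) when exact minimization
  matters.
* The pixel-correlation judge rewards low-level fidelity; semantic quality
  of latent-space reconstructions is outside its sensitivity, which is
  precisely why the full-scale protocol also used human raters.
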