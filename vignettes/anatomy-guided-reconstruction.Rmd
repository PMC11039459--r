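---
title: "Anatomy-guided CT reconstruction from two topograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-guided CT reconstruction from two topograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A CT scanner acquires one or two topograms (scout radiographs) before every
scan. If a coarse 3D volume with reliable organ anatomy could be estimated
from those two projections alone, organ-dose-aware planning (for instance
risk-minimising tube-current modulation) could run *before* the scan instead
of after it. Reconstructing a volume from two views is massively
underdetermined, so the estimator is generative: a conditional GAN maps the
anterior-posterior (AP) and lateral (LAT) fan-beam projections to a volume,
and anatomy-specific loss terms keep the organs it invents in plausible
places with plausible boundaries.

`topo2ct` implements this pipeline end to end in R: the fan-beam geometry
operators, a labelled synthetic thorax corpus, the dual-encoder generator
with geometry-based 2D-to-3D feature lifting, a least-squares patch
discriminator, a frozen 3D U-Net organ segmenter used both as a training
loss and as the inference-time segmenter, the composite objective, and the
evaluation protocol (PSNR, SSIM, RMSE in HU, per-organ Dice under two
reference conventions). No external deep-learning framework is used: the
convolution engine (im2col + GEMM, with hand-derived backward passes) is part
of the package and is verified by finite-difference tests.

## Acquisition model

Fan-beam geometry is per-slice: for every vertical position z, rays diverge
from a point source (source-to-isocenter distance SID = 595 mm) to a flat
detector row (source-to-detector distance SDD = 1085.6 mm, the scanner model
of a Siemens Somatom Force). The AP view places the source on the +y axis,
the LAT view on the +x axis; z is the slice-stacking axis throughout.

Two sparse linear operators derive from this geometry:

* **Forward projector** `build_forward_projector()` — ray-driven
  (Joseph-style) sampling at half the voxel pitch with bilinear in-slice
  interpolation, scaled by the step length in mm, so the projection of a
  unit-valued disk equals its chord length. Used for topogram simulation and
  the projection-consistency loss.
* **Backprojection / lifting matrix** `build_system_matrix()` — pixel-driven:
  each in-slice pixel centre is projected through the source onto the
  detector and linearly interpolated between its two neighbouring channels.
  Rows of pixels falling outside the channel-centre range are all-zero (no
  clamping, to avoid edge smears in lifted features). This matrix lifts 2D
  network feature maps into 3D (`lift_2d_to_3d()`), z row by z row.

Both operators are stored sparse matrices, so each is exactly linear, its
adjoint is its stored transpose (`adjoint_apply()`), and differentiability
through them is trivial. The two are intentionally *unmatched* (ray-driven
forward, pixel-driven back): the pipeline only ever uses backprojection for
feature lifting, never as the numerical adjoint of the projector.

Choices the scanner model does not pin down, decided once here: the detector
is flat (not an arc), and its spacing is derived so that it exactly covers
the magnified field of view (`n_image * voxel_spacing * SDD/SID /
n_detector`), which eliminates truncation deterministically. The scanner's
physical 920-channel fan is supported by setting `n_detector = 920` for
simulation work, but training operators default to the projection resolution
(128 full scale) so the system matrix stays compatible with network feature
maps. The LAT system matrix is built directly in the common (AP) world frame
— backprojecting along x instead of y — which is equivalent to lifting in a
local frame and permuting axes, and saves the permutation.

## Synthetic thorax corpus

`sample_phantom()` draws, deterministically from `(seed, index)`: an
elliptical-cylinder body of soft tissue (a thorax window cut from a torso is
nearly constant in cross-section, which also keeps organ placement always
feasible), two lung ellipsoids, one liver ellipsoid in the lower body, a
vertical spine cylinder and 4–8 rib arcs in bone HU, with labels painted
from the same primitives. Tissue HU values are drawn per phantom from
uniform ranges (air -1000, soft 40±20, lung -800±50, liver 60±15, bone
700±100) plus a small clamped voxel-level texture (sd 5 HU), so every lung
voxel stays below -500 HU and every bone voxel above 300 HU by construction.

One coupling is deliberate: the liver draw is floored a fixed contrast above
the *same phantom's* soft-tissue draw (and clipped into the 45–75 HU range).
With fully independent draws the liver is iso- or hypodense to its
surroundings in a sizeable fraction of phantoms and no intensity rule — and
no segmenter — can identify it, which is unlike real contrast anatomy where
the liver is consistently hyperdense to surrounding soft tissue. The
marginal ranges above are preserved.

What the corpus does *not* emulate: textured parenchyma, pathology,
deformable anatomy, beam physics (scatter, polychromatic spectra, noise).
Tests passing on this corpus therefore demonstrate that the operators,
losses, optimisation and protocol work as specified — not that the trained
weights transfer to clinical data.

## Networks

All features are channels-last R arrays; every layer has a hand-written
backward pass over the compiled conv kernels.

* **Generator** (`generator_forward()`): one 2D U-Net per view (4 levels,
  stride-2 downsampling, nearest-neighbour upsampling, additive skips,
  instance norm + ReLU). At every decoder level the 2D maps are lifted to 3D
  through the level-matched system matrix (grid and detector halved, pitches
  doubled — the physical field of view is unchanged); the AP and LAT lifted
  stacks are fused by elementwise addition and consumed by a single 3D
  decoder ending in a sigmoid, so the output volume lives in [0,1] like the
  normalised targets.
* **Discriminator**: a 3D patch classifier — three stride-2 conv blocks
  (leaky ReLU 0.2, instance norm after the first block) and a 1-channel
  head; one score per receptive-field patch, no global pooling.
* **Organ segmenter** (`segnet_forward()`): vanilla 3D U-Net with five
  downsampling levels and a 4-class softmax head. Two full-resolution convs
  precede the first downsampling (boundary precision is decided at full
  resolution). The input volume is standardised per volume (z-score) before
  the first conv: organ contrasts are well under 1% of the [0,1] HU window
  and standardisation brings them onto a scale the network can amplify; the
  z-score is a smooth map, so gradients flow through it when the segmenter
  is used as a loss.

Widths, depths, normalisation and activation choices follow common
image-translation practice; they are configurable (`base_channels`,
`n_levels`) with a full-scale default (base 64 at 128³) and the desk profile
below.

## Training objective

The discriminator minimises the least-squares loss
`L_dis = ½·E[(D(y)-1)²] + ½·E[D(G(x))²]`; the generator minimises

```
L_G = λ_gen·L_gen + λ_r·L_r + λ_proj·L_proj + λ_s·L_s + λ_p·L_p
```

with `L_gen = E[(D(G(x))-1)²]`, `L_r` the voxel MSE, `L_proj` the mean
squared AP+LAT projection difference, `L_s` the Dice distance between the
frozen segmenter's soft masks of the reconstruction and of the ground truth
(mean over lung, liver, bone), and `L_p` a 3D perceptual distance: both
volumes are sliced along z, each slice replicated to three channels and
passed through a fixed four-level 2D feature pyramid; squared feature
differences are averaged per level, summed over the four levels and averaged
over slices. Default weights are λ_gen = 0.1, λ_r = 10, λ_proj = 10,
λ_s = 2.0, λ_p = 0.5; with λ_s = λ_p = 0 the objective is the plain
image-translation baseline.

Numerical choices worth knowing:

* **Dice form.** The soft Dice is implemented with squared-norm denominators,
  `1 − 2⟨p,r⟩/(‖p‖² + ‖r‖² + ε)`, ε = 10⁻⁶. On hard masks this equals the
  plain-sum form, and unlike it, it is exactly zero for identical *soft*
  masks — the identity the loss contract requires. Segmenter pretraining
  includes the background class in the Dice mean; with foreground-only Dice
  the softmax slack has nowhere to go and collapses onto the weakest
  foreground class (we observed liver predicted on 90% of the volume).
* **Projection scale.** `loss_projection()` itself operates on raw
  line-integral projections. Inside training, the residuals are taken on
  projections divided by the same corpus-level constant that normalises the
  input topograms: raw line integrals on a [0,1] volume have magnitude
  ~50–100 mm, which under λ_proj = 10 would swamp every other term, and
  equal weights for L_r and L_proj only make sense on commensurate scales.
  The scaled operator is still a fixed linear map.
* **Perceptual norm and aggregation.** The feature distance is squared-L2
  (an L1 variant sits behind `perceptual_kind = "l1"`); per-level
  aggregation is the mean over feature elements (batch- and slice-count
  independent), under which replicating a slice to three channels is
  neutral. The default extractor uses seeded random He-initialised weights —
  every metric property of the loss (zero at identity, positivity, monotone
  growth with perturbation) holds for any fixed pyramid — and pretrained 2D
  weights can be plugged in via `feature_extractor(params = ...)` for
  full-scale work.
* **Frozen modules.** The segmenter and the extractor are never updated
  during GAN training; the acceptance suite checks both bitwise.
* **Instance norm degeneracy.** At a 32³ training grid the deepest U-Net
  level has spatial size 1, where instance normalisation maps everything to
  zero; that level is then inert and the surrounding levels carry the model.
* **Output initialisation.** The generator's final conv is initialised at a
  tenth of the He scale so the sigmoid starts near mid-range for every seed;
  with full-scale initialisation some seeds begin saturated and waste many
  epochs escaping the flat region of the sigmoid.

Optimisation: Adam (β₁ = 0.5, β₂ = 0.999 — the usual GAN setting), learning
rates 2·10⁻⁴ (GAN, 100 epochs full scale) and 5·10⁻⁴ (segmenter, 200 epochs
full scale), one discriminator step per generator step, batch gradients
averaged. Both updates in a step are computed against the same pre-update
discriminator state. All randomness (initialisation, data order) derives
from the config seed, so runs are bitwise reproducible; per-epoch
checkpoints carry parameters, optimiser state, history and the RNG state,
making interrupted runs resumable bitwise.

## Preprocessing

Real volumes pass through trilinear resampling (optionally via 1 mm to
2.5 mm), centre crop / air-pad to the cubic grid, and affine HU windowing to
[0,1]. The window default is the 12-bit CT range [-1024, 3071] — the exact
window is not dictated by the method, but it must be fixed per run and
invertible (RMSE is reported in HU through the stored window). Topograms are
simulated by forward projection of the normalised volume and divided by a
single corpus-level maximum stored in the run config; per-image scaling
would destroy the attenuation-magnitude cues the generator relies on.
Phantoms are generated natively at the target grid, so the resampling stage
is exercised by tests but skipped in the synthetic pipeline.

## Evaluation protocol

`evaluate_reconstruction()` computes PSNR (data range 1 on normalised
volumes), SSIM (3D, Gaussian window σ = 1.5, width 11, borders cropped;
cross-checked against a slice-wise 2D reference implementation), RMSE in HU,
and per-organ Dice twice: **M-analog** — segmenter masks of the
reconstruction against the phantom's own labels (the stand-in for manual
annotations), and **S-analog** — against the segmenter's masks of the true
volume. S-analog is structurally the easier reference (prediction and
reference share the segmenter's biases), so S ≥ M is the expected ordering.
Empty-class conventions: absent from both masks → 1, absent from exactly one
→ 0.

## Desk-scale profile and what the bench shows

Full-scale training (128³, base 64, hundreds of volumes) is a GPU-scale
computation and is not what the test suite runs. The package's bench — the
`desk_config()` profile — exercises the entire pipeline on one CPU:

* segmenter recovery: 24 phantoms at 64³, base 4, batch 1, 20 epochs of the
  Dice/Adam recipe; held-out mean foreground DSC is the reported quantity;
* GAN behaviour: 16 phantoms at 32³, base 8, batch 4, 10 epochs (loss
  decrease, baseline reduction, determinism);
* anatomy-enhancement trend: three seeds × {baseline, λ_s = 2.0,
  λ_p = 0.5} on 12 phantoms at 32³, 5 epochs each, evaluated on a shared
  held-out split;
* `scripts/acceptance.R` replays a reduced version of the same pipeline (20
  phantoms at 32³) end to end from a single seed.

These sizes are the package's own benchmark choices: large enough for the
qualitative behaviours (training progress, the direction of the anatomy
effect, S ≥ M) to be visible, small enough to rerun routinely. They do not
reproduce the paper-scale benchmark numbers of the original study, and are
not meant to.

## Known limitations

* The generator's connection details beyond its described topology (two
  pathways, per-level lifted fusion by addition, one 3D decoder) are this
  package's choices; no parity with any specific reference implementation is
  claimed.
* The default perceptual extractor is a random fixed pyramid, not a
  natural-image-pretrained network; at desk scale this is a feature (no
  heavyweight dependency), at full scale pretrained weights are expected to
  help and can be supplied.
* Fan-beam (not cone-beam) geometry: rays never cross z planes, which is an
  approximation to scout-view physics shared by the acquisition model the
  operators are built on.
* Liver-soft-tissue contrast in the corpus is enforced rather than emergent;
  segmentation difficulty on real abdominal CT is substantially higher.
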