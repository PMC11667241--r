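---
title: "Motion-compensated 4D-CBCT reconstruction with deep groupwise registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-compensated 4D-CBCT reconstruction with deep groupwise registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiration-resolved cone-beam CT (4D-CBCT) sorts the projections of a
one-minute scan into N respiratory phase bins and reconstructs one volume
per bin. With roughly 1/N of the projections per phase, filtered
backprojection (FDK) produces severe streak artifacts from angular
undersampling. Motion-compensated (MoCo) reconstruction removes the
undersampling by using *all* projections for every target phase: each
projection is backprojected along trajectories warped by an inter-phase
motion model, so anatomy acquired in phase j is deposited where it sits in
the target phase i. The quality of the result rests entirely on the motion
model, and conventional deformable registration is far too slow to build
one at treatment time. This package implements the fast alternative: a
deep groupwise registration that estimates all phase-to-template
displacement fields at once, either by one-shot optimization on the images
at hand (patient-specific) or by a single forward pass of a pre-trained
population model, preceded by a self-supervised streak-artifact-reduction
network that cleans the initial phase images enough for reliable
registration.

Everything is exercised end-to-end on a synthetic deformable thorax
phantom with analytically known motion, so every stage has a ground-truth
oracle.

## Pipeline

1. `simulate_scan()` (or real projections): cone-beam line integrals with
   per-projection angle and timestamp.
2. `extract_respiratory_signal()`: Amsterdam-Shroud surrogate from the
   projections themselves.
3. `phase_bin()`: peak-anchored phase fractions and N = 10 bins.
4. `reconstruct_phase_images()`: the initial "4D FDK" images.
5. `make_training_pairs()` + `train_artifact_reduction()` +
   `apply_artifact_reduction()`: per-scan self-supervised streak removal.
6. `one_shot_register()` or `train_population()`/`predict_dvfs()`:
   groupwise displacement fields to the implicit template.
7. `build_motion_model()`: all inter-phase transforms by inversion and
   composition.
8. `moco_reconstruct_4d()`: warped-backprojection FDK for every phase.
9. `compute_tre()`, `rmse_mean_aligned()`, `psnr()`,
   `ssim_optimal_scale()`, `evaluate_pipeline()`: evaluation.

## The groupwise registration model

The N normalized phase images \(I_n\) are registered jointly to an
*implicit template* \(I_{tem}\), the voxelwise mean of the warped inputs,
rather than to any chosen phase; this avoids biasing the motion model
toward one respiratory state. The network maps the channel-concatenated
phase images to N displacement fields \(D_n\) (voxel units, pull
convention: the warped value at voxel p is sampled at \(p + D_n(p)\)).
The training loss is

* **similarity**: minus the mean squared local normalized
  cross-correlation (LNCC, window 5^3, stabilizer 1e-5 in the
  denominator) between each warped image and the template;
* **spatial smoothness** (weight `lambda1 = 1`): bending energy, the mean
  squared second forward difference of each displacement component along
  each axis;
* **temporal smoothness** (weight `lambda2 = 1e-5`): squared forward
  difference along the phase axis, wrapped cyclically because respiration
  is periodic (a non-cyclic variant is a config switch);
* **zero mean deformation** (weight `lambda3 = 5e-2`): the root mean
  square of the per-voxel sum of all N fields, which pins the implicit
  template to the center of the motion.

A note on the similarity normalization: the package defaults to the
*voxel-count-normalized* LNCC (mean squared local correlation, in
\([-1, 0]\) after negation). With the raw sum over voxels the similarity
is of order \(|\Omega| \sim 10^5\) while all three regularizers are
normalized per voxel, so the stated weights would be effectively zero; in
that regime the optimization drifts into large unphysical fields whose
fixed-point inversion fails. The normalized similarity puts all four terms
on a commensurate per-voxel scale, which is what makes the default
weights meaningful. The raw-sum variant remains available via
`registration_config(normalized_lncc = FALSE)` for experiments, with the
caveat that the regularization weights must then be rescaled by the voxel
count.

### Network

A compact 3D U-Net/ResNet hybrid (`network_spec()`): the input stack is
average-pooled by a factor 4 to an internal grid, passed through a stem
convolution, four encoder residual blocks on two resolution levels
(channel widths 16/32), a decoder with a skip connection and three
residual blocks, and a final convolution to 3N displacement channels that
are trilinearly upsampled back to the image grid. All convolutions are
kernel-3 with instance normalization (without learnable affine
parameters) and leaky ReLU (slope 0.2). The final layer is
zero-initialized so the untrained network predicts exactly the identity
transform. Forward and backward passes are hand-derived (no external deep
learning framework); the gradient of every term, including the LNCC with
its replicate-padded box filters, is exact and is verified against finite
differences in the test suite.

The internal downsampling and the modest widths are deliberate: breathing
displacement fields are smooth at the scale of centimeters, so a coarse
parameterization loses little accuracy while keeping one-shot CPU
training in the minutes range. Width/level counts are configuration, not
architecture constants.

### One-shot and population modes

*One-shot* (patient-specific): the network is trained from scratch on the
single image set being registered, Adam at `1e-3`, batch 1; the
optimization itself produces the displacement fields. Convergence is
declared when the loss moves less than `1e-5` from the moving average of
the previous 20 iterations; a 3000-iteration cap prevents hangs. On the
desk-scale phantom convergence typically takes 100-250 iterations.

*Population*: the same loss is optimized over a collection of phase-image
sets for a fixed 200 epochs; the trained network is then applied to an
unseen set in one forward pass. With five simulated phantoms varying in
tumor position, body size and breathing amplitude, the model halves or
better the landmark TRE of an unseen sixth phantom without any
per-patient optimization.

### Motion model algebra

The inter-phase transform from phase i to phase j composes the
template-to-j field with the *inverse* of the template-to-i field.
Inversion uses fixed-point iteration (`D_inv(p) <- -D(p + D_inv(p))`,
stop at 0.01 voxel or 50 iterations, with divergence detection), and
composition samples the outer field trilinearly. Pair fields are composed
on demand from the N stored fields and their N precomputed inverses
rather than materializing all N^2 fields; for N = 10 at clinical grids
that is the difference between ~50 MB and ~5 GB.

## Self-supervised artifact reduction

Streak patterns depend on the angular distribution of the projections in
a bin, not on the respiratory state. *Pseudo-average* bins exploit this:
pseudo bin b takes, from breathing cycle c, the projections whose phase
label is (b + c) mod N. Each pseudo bin therefore has a phase-bin-like
(undersampled) angular distribution but time-averaged motion content, so
its FDK reconstruction pairs naturally with the all-projection
(time-average) FDK image: same anatomy, different artifacts. The
round-robin rule is our choice where only the mixing property is
prescribed; it is deterministic and balances phases exactly. A small
residual 3D encoder-decoder (stem convolution at full resolution, two
residual blocks at half resolution, skip connection, residual output) is
trained per scan with mean absolute error on these pairs and applied to
the phase images.

On the desk-scale phantom the denoiser clearly improves the lung region
(the motion-relevant one, and one of the standard evaluation ROIs) for
every phase, while over the whole body it can score slightly worse than
its input because the small network blurs the thin rib shells. The
evaluation functions therefore take an explicit ROI, and the package's
own end-to-end checks use the lung mask.

## The synthetic phantom and what it does (not) show

`phantom_spec()` is an analytic thorax: body ellipsoid, two lung
ellipsoids truncated by a diaphragm dome, a tumor sphere, vessel
cylinders and rib-like bony shells, with attenuations in mm^-1 at CBCT
energies (lung 0.005, soft tissue 0.020, tumor 0.024, bone 0.040). The
breathing model is a one-parameter surrogate: amplitude function
`a(phi) = sin^2(pi phi)` (end-exhale at phi = 0, peak inhale at 0.5) and
a spatial weight field `u(p)` that is superior-inferior dominant with a
cosine-squared falloff from the diaphragm apex to the lung apex, a 20%
anterior-posterior component, and a smoothstep taper to zero at the body
surface (taper width 0.43 in normalized ellipsoid coordinate). The taper
makes `u` continuously differentiable with `||u|| = 1` exactly at the
diaphragm apex, so the peak diaphragm excursion equals the amplitude
parameter and fixed-point pull-backs converge with a comfortable
contraction margin up to 15 mm amplitude.

Default study conditions: 64 x 64 x 48 voxels at 4 mm ("desk scale"; the
full clinical 224 x 224 x 96 at 2 mm grid is available through
`grid_spec()`), SID 1000 mm / SDD 1500 mm full-fan circular geometry, 180
projections evenly over 360 degrees in 60 s, 4 s breathing period (15
cycles), 10 mm amplitude, 10 phases, noiseless by default with
transmission-domain Poisson noise available (`photons_I0`; Gaussian
approximation above 1000 counts). Projection simulation quantizes the
breathing cycle into 20 discrete motion states and ray-traces each state
once with exact Siddon traversal, which keeps chord-length oracles tight
and the simulation tractable.

What the phantom does *not* emulate: scatter, beam hardening, bowtie
filters, detector lag, half-fan acquisitions, hysteresis
(inhale/exhale asymmetry), cycle-to-cycle amplitude drift, and real
anatomical texture. Passing tests therefore demonstrate correctness of
the algorithms and recoverability of smooth periodic motion, not clinical
image quality. Two further simulator artifacts matter for interpreting
the checks: the 4 mm voxelization adds broadband "moire" jitter of a few
percent to the shroud surrogate of a *static* scan (the no-motion control
in the tests is rasterized at 2 mm for this reason), and the phase-origin
convention anchors fraction 0 at the surrogate peak, which for this
phantom is the resting (end-exhale) state, so extracted fractions are
directly comparable with the simulator's ground truth.

## Numerical choices

* FDK: DC-free closed-form Ram-Lak kernel (optional Hann), rows padded to
  twice their length with *edge replication* - zero padding would turn a
  constant row into a rect and filter it to nonzero values; detector
  coordinates rescaled to the isocenter; `SID^2/U^2` distance weighting;
  per-projection angular weights equal to half the circular gap so
  unevenly thinned (phase-binned) subsets are normalized correctly.
* MoCo backprojection processes projections in acquisition order with a
  per-projection phase label selecting the displacement field, so the
  identity motion model reproduces plain FDK bit for bit.
* LNCC means/variances via exact replicate-padded box sums (sliding
  sums), with the exact adjoint used in the gradient.
* Box/warp/resample kernels, the 3D convolutions and their backward
  passes are C++ (Rcpp); everything is single-threaded and deterministic,
  and every stochastic entry point takes an explicit seed (one-shot and
  population training are bit-reproducible under a fixed seed).
* Intensity normalization clips to the 0.5/99.5 percentiles and maps to
  [0, 1]; training pairs share the target's affine so input and target
  live on one scale; the affine is returned for exact inversion.
* Degenerate inputs: constant volumes normalize to zero with a warning;
  fewer than two detected breathing peaks, empty phase bins, half-fan
  geometry, heterogeneous population grids and diverging field inversions
  raise descriptive errors.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely at desk scale: the
64 x 64 x 48 / 180-projection scan above for signal extraction, 4D FDK,
artifact reduction and MoCo; a 4-phase, 8 mm amplitude variant for
one-shot parameter recovery; and six 32 x 32 x 24 (8 mm) phantoms for the
population experiment (five for training, one held out). These sizes are
the package's default study conditions; all of them scale up through
configuration only.

## Known limitations

* Full-fan circular trajectories only; no Parker weighting (fixed 360
  degree arc), no truncation correction.
* No Jacobian intensity correction in the warped backprojection (the
  motion model deforms trajectories but conserves projection values).
* Single-resolution registration; no diffeomorphic parameterization -
  large or sliding motion is out of scope.
* The denoiser is deliberately small; at clinical grids it should be
  patch-trained and widened (both are configuration).
* On this phantom, motion-compensated images retain the FDK noise floor,
  so the artifact-reduced (smoothed) images can have lower lung RMSE than
  MoCo in some conditions even though MoCo restores structure that the
  denoiser blurs; image error alone understates that difference.
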