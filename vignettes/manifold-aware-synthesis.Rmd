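---
title: "Manifold-aware synthesis of diffusion MRI: methods and design"
author: "dmrisynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manifold-aware synthesis of diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrisynth)
```

## The problem

Diffusion-weighted MRI is acquired at a coarser resolution than structural
T1-weighted imaging (typically 1.25 mm versus 0.7 mm isotropic), and paired
high-resolution diffusion data essentially do not exist. This package
implements a synthesis framework that translates a high-resolution scalar
structural volume into a high-resolution diffusion volume — either a
diffusion tensor (DT) field or a field of orientation distribution functions
(ODFs) — while *guaranteeing* that every synthesized voxel is mathematically
valid. The guarantee is architectural, not learned: networks never touch the
curved spaces the data live on.

## Two Riemannian frameworks

**Diffusion tensors.** A DT is a 3×3 symmetric positive-definite (SPD)
matrix. The SPD cone is not a vector space: Euclidean operations
(interpolation, convolution, gradient steps) can leave it, producing
physically meaningless tensors, and Euclidean averaging inflates
determinants (the swelling effect). Under the log-Euclidean metric a tensor
$M = U \Sigma U^\top$ is mapped to the flat tangent space at the identity by
$\log(M) = U \log(\Sigma) U^\top$; any *symmetric* matrix $S$ maps back to
an SPD tensor through $\exp(S)$, and the geodesic distance is
$\|\log(P_1)-\log(P_2)\|_F$. All Euclidean processing in this package — the
networks, trilinear resampling, the $\ell_1$ losses — happens on the log
side; `tensorExp()`/`fieldExp()` then cannot produce a non-SPD voxel, for
*any* network weight state. Because network outputs are symmetrized
channel-wise before the exponential (`unpackChannels(symmetrize = TRUE)`),
no eigendecomposition ever needs to be differentiated.

**ODFs.** An ODF is a probability density on the sphere. Its square root
$\psi = \sqrt{p}$, expanded in a real symmetric spherical-harmonic (SH)
basis of order $L$, is a unit-norm coefficient vector $c$ on the sphere
$\mathbb{S}^{K-1}$ with $K = (L+1)(L+2)/2$ (15 for the order-4 basis used
throughout). The uniform distribution is $u = (1, 0, \ldots, 0)$;
`odfLog()`/`odfExp()` are the closed-form sphere maps at $u$, the geodesic
distance is the Euclidean distance of tangent projections, and the
generalized fractional anisotropy is $\mathrm{GFA} = \sqrt{1 - c_1^2}$ for
unit-norm $c$. `odfExp()` returns a unit vector for every tangent input
(any component along $u$ is projected out first), which is the ODF-side
validity guarantee. The printed form of the GFA formula in the source
literature is typographically ambiguous; we implement the standard
Tuch-consistent normalized form on the coefficients of $\psi$, which is the
only reading for which "distance from the uniform distribution" holds.

## Synthesis architecture

Two generators and two discriminators form an unpaired cycle-consistent
adversarial pair: $G_Y$ maps structural patches (32³ voxels at 0.7 mm; the
desk configuration uses 12³) to log/tangent diffusion patches on the same
grid; $G_X$ maps upsampled log/tangent diffusion back to structural.
Because real diffusion exists only at low resolution, a *residual
downsampler* $F$ — fixed trilinear resampling to the LR grid plus a
three-layer learned convolutional correction, zero-initialized so that it
starts as pure interpolation — reduces synthesized HR diffusion before the
diffusion discriminator sees it. The objectives are least-squares GAN
losses, a three-term cycle loss (structural cycle; HR diffusion cycle;
LR diffusion cycle through $F$), and a paired prior on a small number of
aligned subjects, all with $\ell_1$ voxel errors in the log/tangent domain.
The diffusion error terms are weighted per voxel by the FA/GFA of the
*target* volume, floored at 0.05 so isotropic tissue is down- but never
zero-weighted (whether such weights should be renormalized is unspecified
in the source; we use the raw floored values). Loss weights default to
$\lambda_{\mathrm{prior}X}=10$, $\lambda_{\mathrm{prior}Y}=0.5$,
$\lambda_{\mathrm{cyc}X}=5$, $\lambda_{\mathrm{cyc}Y}=0.25$.

The generator-side adversarial term uses the standard LSGAN form
$\tfrac12(D(\mathrm{fake})-1)^2$. Updates follow simultaneous per-batch
alternation: one forward pass per sample provides both the discriminator
gradients (fakes detached) and the generator gradients (flowing through the
pre-update discriminators); both players then step with Adam (learning rate
$10^{-4}$, $\beta_1 = 0.5$, $\beta_2 = 0.999$, batches of 8, a
reduce-on-plateau scheduler with patience 10 that multiplies the learning
rate by 0.1). "Factor of 10" is interpreted as multiply-by-0.1, the
standard reduce-on-plateau semantics. Because adversarial training
oscillates, the trainer additionally evaluates a *fixed* validation patch
set every `valInterval` steps (default 50) and returns the weights of the
best-validation snapshot rather than the last step -- standard checkpoint
selection, with the validation set drawn once so that snapshots are
compared on identical data and validation never perturbs the training
sampling stream.

Full-volume inference tiles the structural volume with 50%-overlapping
patches, blends the log/tangent outputs under a cosine (Hann) window, and
maps once to the manifold. Blending happens *before* the exponential so the
blend is itself a tangent-space (geodesically meaningful) average, and the
output remains 100% valid.

### The networks

The generators are compact 3D U-Nets (encoder–decoder with skip
connections); the discriminators are strided-convolution critics with
feature widths (32, 64, 128, 256) at full scale, emitting one score per
volume. The final activations are modality-specific: sigmoid for structural
outputs ([0, 1]); a hard (saturating) tanh for DT log-domain outputs, whose
bound must cover the data's log-eigenvalue dynamic range — with the
phantom's diffusivities the log eigenvalues span roughly ±2.3, and the
default bound 3 adds ~20% margin; a smooth tanh for ODF tangent outputs.
Generator block convolutions are followed by per-channel instance
normalization (standard in unpaired-translation generators and the
batch-size-1 analogue of the batch normalization used by 3D U-Nets), which
conditions the short desk-scale optimization; the output head is
initialized at one-twentieth of the He scale, so an *untrained* generator
synthesizes the manifold base point (near-isotropic tensors, near-uniform
ODFs) rather than arbitrary anisotropy — a well-defined reference state for
learning comparisons, and a gentle start for the adversarial game. The
internal widths and depths of the exemplar architectures are not fully
specified in the source literature, so the configurations here are our own;
parameter counts are reported by `nParams()` but never asserted against
published totals. The engine (im2col + GEMM convolutions with hand-written
backpropagation and Adam) computes convolutions in single precision — the
step is memory-bound and the training signal is stochastic; a
double-precision path (`options(dmrisynth.convSingle = FALSE)`) exists and
is used by the exact finite-difference gradient tests.

## The phantom: what it emulates and what it does not

`makePhantom()` builds paired structural + diffusion volumes with known
ground truth: tubular fiber bundles with axially symmetric tensors oriented
along the local centerline tangent. Given a target FA $f$ and mean
diffusivity $m$, the eigenvalues are solved in closed form:
$\lambda_1 = m(1+2\delta)$, $\lambda_{2,3} = m(1-\delta)$ with
$\delta = f/\sqrt{3-2f^2}$ (feasible for all $f < 1$). Diffusivities are
expressed in μm²/ms so white matter has MD ≈ 0.7 and log-eigenvalues sit
near zero — numerically convenient and unit-consistent. Crossing voxels
receive the log-Euclidean mean of the bundle tensors (a DT cannot represent
a crossing, matching real DT behavior) and a two-peak ODF built as an equal
mixture of the two single-fiber ODFs. Background tissue is mildly
anisotropic (FA 0.1) with random per-voxel orientation; an optional CSF
ball has high diffusivity and near-zero FA.

Single-fiber ODFs use the Gaussian model
$p(s) \propto (s^\top D^{-1} s)^{-3/2}$, *sharpened* by subtracting 85% of
the isotropic floor before the square-root SH fit. The raw Gaussian dODF is
blunt (GFA saturates near 0.37 even at FA 0.8), whereas the sharpened
constant-solid-angle reconstructions used in practice reach much higher
GFA; the sharpening brings bundle GFA to ≈ 0.55–0.65 so that the standard
GFA ≥ 0.5 evaluation mask is meaningful. Structural intensity is a
deterministic function of tissue class and local anisotropy
(WM ≈ 0.55 + 0.35·FA, GM 0.45, CSF 0.12) with a smooth multiplicative bias
field and Gaussian noise (SD 0.02), clipped to [0, 1] — the premise that
brain geometry predicts fiber organization is thus embedded by
construction, which is what makes the synthesis task learnable at desk
scale.

What the phantom does **not** emulate: MR physics (no Rician noise, no EPI
distortion), anatomical realism, tissue heterogeneity within bundles, or
the ill-posedness of real structural→diffusion inference (where one T1w
intensity maps to many fiber configurations). Passing tests on phantoms
therefore demonstrate the *mechanics* of the framework — validity
guarantees, metric behavior, learnability of a constructed mapping — not
clinical synthesis quality.

Low-resolution data are simulated by `degradeToLR()`: Gaussian anti-alias
filtering (σ = ½√(r²−1) voxels for resolution ratio r) and trilinear
resampling, both in the log/tangent domain, so degraded volumes remain
valid and interior anisotropy can only decrease (partial-volume behavior).

## Numerical choices

* **Eigenvalue floor.** `tensorLog()` clamps eigenvalues at $10^{-8}$
  (diffusivity units) before the scalar log: background voxels in real data
  are near-singular and $\log 0 = -\infty$. The handling of such voxels is
  not specified in the source literature; this is our choice.
* **FA of the zero tensor is 0**, not NaN, so background voxels cannot
  poison masked means.
* **arccos clamping.** Dot products are clamped to [−1, 1] before arccos;
  floating-point products exceed the domain by ~1e−16.
* **Symmetry and SPD tolerances.** Symmetry is accepted within
  $10^{-6}\|M\|_F$; validity counting uses strict positivity
  (`eigTol = 0`), the mathematical claim.
* **Sign conventions.** Principal directions are sign-normalized (first
  nonzero component positive); evaluation uses absolute cosine similarity,
  so the convention only makes tests deterministic.
* **724-vertex sphere.** `sphereTessellation()` joins a 362-point Fibonacci
  spiral on the upper hemisphere with its antipodes: deterministic,
  antipodally symmetric, ~7–8° vertex spacing. Peak extraction and the
  discrete-argmax principal direction depend only on symmetry and
  resolution, not on the exact vertex set.
* **ODF non-negativity** of the reconstructed amplitude is *checked and
  reported* (`odfValidity()`), never enforced: the sphere exponential
  guarantees unit norm but nothing in the pipeline forbids negative
  amplitudes, so the package surfaces them as a diagnostic. Validity
  counting uses the unit-norm constraint.
* **Degenerate directions.** Tensor voxels with relative eigenvalue gap
  below tolerance and ODFs whose max/mean squared amplitude ratio is below
  1.05 have no meaningful direction; they are excluded from cosine means
  (count reported) — the only convention that keeps the metric in [0, 1].

## Desk-scale configuration and problem sizes

The full-scale configuration (32³/18³ patches, base width 8+, 50,000
patches per group) targets GPU training and is retained as the default of
`runConfig()`. All experiments the package actually runs use
`deskRunConfig()`: 12³ HR / 7³ LR patches (the same 0.7/1.25 mm physical
extent relation, 8.4 vs 8.75 mm), depth-2 U-Nets of base width 2 with two
convolutions per block — depth 2 so the receptive field spans more than a
bundle diameter (≈4.5 mm at 0.7 mm spacing), which a depth-1 network barely
covers — discriminator widths (4, 8, 16, 32), downsampler hidden width 4,
and Adam at $10^{-3}$: with Adam, no parameter can move farther than
(steps x rate) from its initialization, so the 500-step desk schedule needs
a rate near $10^{-3}$ for the output head to even span the log-eigenvalue
range of the data; instance normalization keeps the adversarial game stable
at that rate. The learning experiment
(`learningExperiment()`) trains the full adversarial system for 2 epochs
over 2,000 patch pairs (batch 8) on a 10-subject, 3-bundle phantom dataset,
and compares the synthesized volume of a held-out subject against the
upsampled reference diffusion — trained versus the same network's initial
weights — on the GFA/FA ≥ 0.5 mask. Validity sweeps use a 48³ phantom;
tractometry sanity uses the straight-bundle phantom at the standard
tracking parameters (step 0.5 mm, max angle 60°, 2 seeds per voxel, 10–300
mm length bounds).

## Tractography

`track()` is a minimal deterministic peak-following propagator in the EuDX
family, not a replication of any specific implementation: fidelity to the
tracking *parameters* is the contract. DT tracking follows the principal
direction of the trilinearly interpolated log-tensor field (interpolating
in the log domain avoids swelling and sign problems); ODF tracking follows
the discrete maximum of the nearest voxel's ODF that is best aligned with
the incoming direction, allowing crossings to be traversed. Seed points are
jittered inside seed voxels by a seeded RNG; repeated tracking with
different seeds is exposed via the CLI (`--repeats`). Density masks are
binary (a voxel is occupied if any streamline point falls in it), matching
the overlap/overreach/Dice definitions, which operate on binary masks.

## Known limitations

* The desk-scale GAN is demonstrative: two epochs of a width-2 network
  cannot saturate even the phantom task, and no hyper-parameter search is
  attempted.
* DT fields cannot represent crossings; the phantom reproduces this
  limitation faithfully rather than working around it.
* Single-precision convolutions introduce ~1e−7 relative arithmetic noise;
  all manifold mathematics (log/exp maps, metrics, resampling) remains in
  double precision.
* The TRK writer targets the common diagonal-affine case; exotic
  orientations round-trip through the stored affine but are untested
  against third-party viewers.
* Training runtime is dominated by memory-bound small-channel 3D
  convolutions; at full scale (32³ patches, width ≥ 8) a GPU framework
  would be the right tool.
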