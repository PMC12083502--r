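---
title: "Blood-flow tomography with dcflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-flow tomography with dcflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcflow)
```

## What the package models

Diffuse correlation tomography (DCT) images microvascular blood flow by
measuring how fast the speckle pattern of multiply scattered
near-infrared light decorrelates. Red blood cells are the dominant moving
scatterers; their motion is summarized per voxel by the blood flow index
(BFI) `alphaDb` in cm²/s. The measurement is the normalized intensity
autocorrelation `g2(tau)` of each source–detector (S-D) channel, related
to the electric-field autocorrelation `g1(tau)` by the Siegert relation
`g2 = 1 + beta * g1^2`, with `beta` the coherence factor of the detection
optics.

`dcflow` implements a complete, desk-scale synthetic pipeline:

1. **Phantoms** — a voxelized 8 × 8 × 3 cm breast-like slab (0.5 cm
   cubic voxels, 16 × 16 × 6) with spherical lesions of configurable
   diameter, flow contrast and within-lesion heterogeneity.
2. **Photon Monte Carlo** — a random walk through the voxel grid that
   records, for every detected photon, its weight and its exact path
   length in every voxel it crossed.
3. **Forward model** — the exact Monte Carlo integral form of `g1`:
   `g1(m,j,tau) = sum_q w(q) exp(-2 tau sum_i k0^2 alphaDb(i) s(i,q) mus')`,
   plus the Siegert transform, additive correlator noise and the
   acquisition schedule (8 switch positions × 6 parallel detectors ×
   15 curves at 1 Hz = 720 raw curves in 120 s, averaged to 48 curves).
4. **Reconstruction (NL-DCT)** — Taylor-linearizing the exponential in
   `tau` turns the forward model into a linear system
   `A alphaDb = b`, with `A[(m,j),i] = 2 k0^2 mus' sum_q w(q) s(i,q)`
   and `b` the early-delay decay slope of each channel; the system is
   solved with split-Bregman total-variation (TV) regularization under a
   nonnegativity constraint, optionally iterating an order-2..N
   correction; the volume is finally normalized to its mean (relative
   BFI, rBFI).
5. **Imaging** — the depth-layer-2 slice (0.5–1 cm, where sensitivity is
   best) is upsampled 16 → 150 by nearest neighbor, mapped through the
   diverging cool-to-warm colormap, round-tripped through 8-bit TIFF,
   and bicubically resized to a 3 × 224 × 224 tensor.
6. **Features and classification** — 12 image features (local perfusion:
   maximum, minimum, FWHM threshold, mean above FWHM; heterogeneity:
   variance, CV, range, skewness, IQR, GLCM contrast and energy,
   histogram entropy), an RBF-SVM with grid-searched `(C, gamma)` under
   stratified five-fold cross-validation, 20 repeated stratified 39/20
   splits, six evaluation metrics and an aggregate rank score.

## Key parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `mus_prime` | 8.0 | cm⁻¹ | breast-tissue reduced scattering |
| `mua` | 0.05 | cm⁻¹ | breast-tissue absorption |
| refractive index / anisotropy | 1.37 / 0.9 | — | breast tissue |
| wavelength | 785 | nm | typical long-coherence DCS laser |
| background BFI | 4.5e-8 | cm²/s | healthy-breast level |
| probe | 8 sources r = 3 cm, 6 detectors r = 1 cm | — | concentric rings; S-D separations 2–4 cm probe depths of ~0.5–1 cm |
| acceptance radius | 0.25 | cm | half a voxel edge: voxel-scale resolution |
| `beta` | 0.5 | — | single-mode fiber detection |
| delay grid | 96 points, 1e-8–1e-1 | s | multi-tau-style; reaches 10 ns so high-flow channels keep several early bins |
| noise `sigma` | 5e-3 | — | flat per-bin Gaussian on `g2` |
| slope window | `1 - g1 < 0.1` | — | keeps the first-order Taylor bias of the through-origin slope below ~5% (`(1-e^{-x})/x ≥ 0.95` ⟺ `x ≤ 0.103`) |
| `mu` (fidelity) | 300 | — | L-curve elbow on a calibration phantom pair (see below) |
| `lambda` (splitting) | 5 | — | convergence speed only |

## Monte Carlo transport

Scattering defaults to the similarity relation (isotropic phase function
at `mus = mus_prime`), with Henyey–Greenstein (`g = 0.9`,
`mus = mus_prime / (1 - g)`) available; in the diffusive regime probed at
2–4 cm separations the two agree and the reduced model is an order of
magnitude faster. Boundaries are index-matched (no Fresnel reflection);
absorption is applied as continuous weight attenuation
`exp(-mua * path)` with no roulette, so path-length statistics — the
quantities the reconstruction consumes — are unbiased. Voxel crossings
use the Amanatides–Woo incremental traversal, making the per-voxel path
sums exact (they reproduce each photon's total path to machine
precision).

Validation is against the closed-form semi-infinite diffusion-theory
reflectance (extrapolated-boundary dipole, `A = 1`), coded independently
of the transport kernel. The comparison is run on a 24 × 24 × 12 cm slab
with a central source so that the semi-infinite assumption holds; on the
8 × 8 × 3 cm imaging slab itself, side and bottom losses legitimately
depress the reflectance and the closed form no longer applies. At the
default optics the kernel agrees within a few percent for separations of
2–4 cm (the test bound is 15%).

## Slope extraction and linearization

The first-order system predicts `1 - g1 ≈ b * tau` with
`b = A alphaDb`. The slope is fitted through the origin (the model has no
intercept) over the delay bins where `1 - g1 < 0.1`. This window is an
analytic choice: for a single-exponential decay the through-origin OLS
slope on a geometric grid is biased low by roughly
`1 - (1 - e^{-x})/x ≈ x/2` at window edge `x`, so a 0.1 edge bounds the
truncation bias near 5%, which the noiseless consistency test
(`‖A alphaDb_true - b‖/‖b‖ ≤ 5%`) confirms.

For reconstruction order N > 1, the order-2..N Taylor terms are
evaluated **per photon** from the current flow estimate and subtracted
from `1 - g1` before re-fitting over a wider window (`< 0.6`), inside a
fixed-point loop seeded by the first-order solution (5 outer iterations
or relative change < 1e-3; divergence for three consecutive iterations
returns the best iterate with a warning). Two numerical points matter:

* the fitting window is always selected on the *raw* `1 - g1` — the
  Taylor corrections grow without bound beyond the decay onset and must
  not steer bin selection;
* because detected photons have widely spread path lengths, individual
  `x_q tau` values can exceed the Taylor radius even when the aggregate
  curve has decayed little; the corrections still reduce the
  wide-window fit residual by two orders of magnitude on the default
  phantoms, which the test suite asserts.

## Split-Bregman TV inversion

The reconstruction solves
`min ‖x‖_TV + (mu/2) ‖A x - b‖²  s.t.  x ≥ 0`
with anisotropic 3-D TV (forward differences, reflecting boundaries).
The system is first rescaled: unknowns are expressed in units of the
homogeneous-fit BFI and the data in units of its own mean magnitude, so
`mu` and `lambda` are dimensionless and transfer across phantoms. The
quadratic x-subproblem is solved exactly by a Cholesky factorization of
`mu AᵀA + lambda L` cached across all Bregman iterations (n = 1536 makes
the direct solve cheaper and more accurate than iterative sweeps);
shrinkage updates the split gradients, and nonnegativity is enforced by
projection each outer iteration. The objective is recorded per iteration
and is non-increasing on all regression cases.

`mu` was chosen once by the residual/TV L-curve on a calibration pair —
a homogeneous slab and a 10× single-inclusion phantom at the default
noise level: `mu = 300` sits at the elbow (relative data residual ≈ 6%,
recovered contrast ≈ 9 of a true 10, homogeneous map flat to 1e-3) and
was then frozen. `lambda` only affects convergence speed; 5 converges in
well under the default 100 iterations.

The rBFI normalization divides by the volume mean, so the output is
scale-free: any global calibration error in the solver cancels, which is
why the classification stage consumes rBFI.

## What the synthetic cohort does and does not emulate

`make_cohort()` draws one spherical lesion per subject. Diameters come
from truncated normals (benign 11.4 ± 8.4 mm, malignant 20.4 ± 9.7 mm,
truncated to 3–40 mm — the truncation prevents nonphysical negative
draws from the printed ±SD). Flow contrast is Uniform(2, 5) for
benign-like and Uniform(5, 15) for malignant-like lesions with lognormal
within-lesion texture (log-sd 0.1 vs 0.35), reflecting the observation
that malignant lesions show larger rBFI magnitude and heterogeneity;
contrasts above 10× are documented for malignant tumors. Lesion centers
fall uniformly over the central probe area at depths 0.6–1.2 cm so
lesions overlap the imaged layer. Benign/malignant priors, background
BFI and center placement are modelling choices anchored to the reported
size statistics — no patient-level flow distributions are published.

Deliberately not emulated: curved breast geometry and the chest wall;
optical-property variation across subjects; correlator bin structure,
afterpulsing and dark counts; multi-lesion subjects. Consequently, a
passing synthetic-cohort classification says the *pipeline* preserves
and recovers class-separating flow structure end to end; it says nothing
about clinical accuracy on real patients, and the clinical headline
numbers of the motivating application (≈97% fusion-model accuracy) are
not reproducible without that private cohort. On the default synthetic
cohort the feature-SVM reaches a mean held-out accuracy around 0.85 with
AUC-ROC ≈ 0.94 over 20 replications of the 39/20 split; the exact value
moves by several points across cohort seeds because many benign lesions
are at or below voxel resolution — an honest property of the simulated
physics, not tuned behavior.

One empirical finding is worth flagging: after per-image min-max
quantization, the GLCM textural-contrast feature is dominated by noise
amplification on near-flat benign reconstructions and does not separate
the classes in the malignant-greater direction (heterogeneity is instead
captured by variance and CV, which separate at p < 1e-6). The feature is
kept — it is part of the 12-feature contract — but tests assert its
validity, not a direction.

## Classification protocol details

* Features are z-scored by training statistics; the grid is
  `C ∈ 2^{-5}, 2^{-3}, …, 2^{15}`, `gamma ∈ 2^{-15}, …, 2^{3}` (the
  standard log₂ lattice), selected by mean accuracy under seeded
  stratified 5-fold CV with ties broken toward smaller `C`, then smaller
  `gamma`.
* Probabilities come from Platt-style scaling fitted on out-of-fold
  decision values with smoothed targets; this keeps the whole model
  deterministic under a seed (the underlying SVM library's built-in
  probability machinery is not seedable from R).
* Hosmer–Lemeshow uses 10 probability-decile groups. The reference
  distribution is chi-square with `g` degrees of freedom because the
  evaluated probabilities are always external to the test data (held-out
  sets); the classical `g - 2` reduction, which applies to in-sample
  logistic fits, is available via `fitted = TRUE`. With `g` df the test
  is correctly calibrated on a simulated null (rejection ≈ 5% at the
  0.05 level); with `g - 2` it would reject ≈ 11%.
* Aggregate scoring treats all six metrics (calibration p included) as
  higher-is-better, ranks models per metric in descending order with
  dense ranks starting at 10, shares scores on ties, and sums — a model
  strictly best everywhere scores 60.
* Random-forest importances are impurity-gain values from a seeded
  500-tree forest, normalized to sum to 1.

## Problem sizes used in tests

The shipped test-suite and the acceptance script run the full pipeline at
reduced photon counts chosen so each stage's statistical checks are
stable: 2 × 10⁴ photons/source for the shared cohort tensor, 1 × 10⁵ for
the localization study, 3 × 10⁵ for the reflectance validation and the
full 720-curve protocol demonstration. These sizes reproduce every
qualitative result; production-quality images use 10⁶ photons/source.

## Known limitations

* Reconstruction accuracy degrades below ~1 cm depth coverage of the
  probe's sensitivity; only the layer-2 slice is used for
  classification, matching the physics.
* Sub-voxel (< 5 mm) lesions are frequently invisible at the 0.5 cm
  voxel pitch; they appear in the cohort by design and bound the
  achievable synthetic accuracy.
* Optical properties are fixed and shared between simulation and
  reconstruction; no model mismatch in `mus'`/`mua` is simulated.
* The forward and inverse stages share one photon ensemble per study
  (an "inverse crime" in the strict sense); the Monte Carlo validity
  test against diffusion theory is the independent guard on the
  transport itself.
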