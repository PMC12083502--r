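# dcflow

Diffuse correlation tomography (DCT) of microvascular blood flow, end to
end and fully synthetic-testable: voxelized Monte Carlo photon transport,
autocorrelation-curve synthesis, Nth-order linear image reconstruction
with split-Bregman total-variation regularization, blood-flow image
post-processing, a 12-feature radiomic extractor, and an SVM-based
benign/malignant classification protocol with multi-metric evaluation.

## Who this is for

Researchers in diffuse optics who want a desk-scale sandbox for DCT
instrument and algorithm design: probe layouts, photon-count budgets,
reconstruction regularization, and the downstream image-analysis /
machine-learning chain can all be exercised on labeled synthetic lesion
cohorts, with every stage unit-tested against independent oracles
(closed forms, brute-force enumeration, diffusion theory).

## The model

Light that has multiply scattered through tissue decorrelates as red
blood cells move. Each source–detector pair `(m, j)` measures the
intensity autocorrelation `g2(tau)`, converted to the field
autocorrelation by the Siegert relation `g2 = 1 + beta * g1^2`. With
photon weights `w(q, m, j)` and per-voxel path lengths `s(i, q, m, j)`
from Monte Carlo, the exact forward model is

    g1(m, j, tau) = sum_q w(q, m, j) *
                    exp(-2 tau * sum_i k0^2(i) alphaDb(i) s(i, q, m, j) mus'(i))

where `alphaDb(i)` is the blood flow index (BFI, cm²/s) of voxel `i`,
`k0 = 2 pi n / lambda` and `mus'` the reduced scattering coefficient.
Expanding the exponential to first order in `tau` gives a linear system

    A alphaDb = b,   A[(m,j), i] = 2 k0^2(i) mus'(i) sum_q w(q,m,j) s(i,q,m,j)

with `b` the early-delay slope of `1 - g1`. The inverse problem is solved
as `min ||alphaDb||_TV + (mu/2) ||A alphaDb - b||^2` subject to
`alphaDb >= 0` via split-Bregman iteration (orders N > 1 subtract the
higher Taylor terms inside a fixed-point loop), and the volume is
normalized to its mean to give the relative BFI (rBFI) image used for
classification.

## Worked example

A 16 mm lesion with 10× blood-flow contrast at 7.5 mm depth, imaged with
the default 8-source / 6-detector concentric probe:

```r
library(dcflow)

grid   <- voxel_grid()                 # 16 x 16 x 6 voxels, 0.5 cm edge
optics <- optical_properties()         # mus' = 8, mua = 0.05 cm^-1
probe  <- make_probe()                 # 8 sources x 6 detectors
sens   <- run_monte_carlo(grid, optics, probe,
                          mc_config(n_photons = 2e5, seed = 42))
#> <sensitivity_tensor> 48 pairs, 200000 photons/source, 2011 detected (0 empty pairs)

lesion  <- lesion_spec(center = c(4, 4, 0.75), diameter = 1.6,
                       contrast = 10, texture_sigma = 0.2)
phantom <- make_phantom(grid, background_bfi = 4.5e-8, list(lesion),
                        seed = 7)

frame <- simulate_acquisition(sens, phantom, optics, seed = 1)
#> <acquisition_frame> 48 averaged g1 curves (720 raw, 15 per pair), 120 s schedule

rec <- reconstruct(frame, sens, optics)
#> <rbfi_map> 16 x 16 x 6, range [0.933, 8.815], mean 1

slice <- take_slice(rec, layer = 2)
peak  <- which(slice == max(slice), arr.ind = TRUE)[1, ]
#> peak rBFI 8.81 at voxel (9, 8); lesion center is voxel (8-9, 8-9)

round(compute_features(slice), 3)
#>                  maximum                  minimum                 variance
#>                    8.815                    0.933                    1.020
#> coefficient_of_variation                    range                 skewness
#>                    0.921                    7.881                    7.117
#>      interquartile_range        textural_contrast          textural_energy
#>                    0.002                    4.263                    0.881
#>                  entropy           fwhm_threshold          mean_above_fwhm
#>                    0.313                    4.874                    8.814
```

The acquisition emits the full protocol (6 detectors × 8 switch
positions × 15 one-second curves = 720 raw curves over a 120-s
schedule), the reconstruction recovers the inclusion at the correct
location with close to its true 10× contrast, and the 12 features
quantify the local perfusion peak and its heterogeneity. Labeled cohorts
(`make_cohort()`), the image tensor chain (`dct_image_tensor()`), and
the repeated-split SVM evaluation (`replicate_experiment()`) build on
these pieces; `vignettes/dcflow-methods.Rmd` documents the models,
parameters and numerical choices.

A command-line front end is installed at `inst/cli/dcflow`
(`simulate-cohort`, `mc`, `acquire`, `reconstruct`, `render`,
`featurize`, `classify`, `importance`).

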