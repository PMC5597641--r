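# lifet: sparse tensor encoding and Linear Fascicle Evaluation of structural connectomes

`lifet` evaluates tractography-derived structural brain connectomes against
the diffusion-weighted MRI (dMRI) data they were built from. Tractography
proposes candidate white-matter fascicles; the Linear Fascicle Evaluation
(LiFE) model asks which candidates the measurements actually support, by
predicting the demeaned diffusion attenuation as a non-negative combination
of per-fascicle kernels,

    y(θ, v) = (S(θ, v) − I_v) / S0(v) ≈ Σ_f  w_f · O_f(θ, v),    w_f ≥ 0,

where `O_f(θ, v) = exp(−b θᵀ Q_{f,v} θ) − mean_θ exp(−b θᵀ Q_{f,v} θ)` is
the demeaned stick-tensor kernel of fascicle `f` at its local orientation
in voxel `v`. Stacked over voxels and directions this is a huge linear
model `y ≈ M w`; `lifet` never materializes `M`. Instead the connectome is
encoded as a sparse three-way array `Φ` (orientation atom × voxel ×
fascicle) paired with a precomputed kernel dictionary `D`, so that
prediction is a cheap tensor contraction and the model shrinks by one to
two orders of magnitude. The non-negative weights are estimated by a
matrix-free projected-gradient Barzilai–Borwein solver; fascicles with
positive weight form the *optimized connectome*, and their count is the
*connectome resolution*.

On top of the fit the package provides:

* **virtual lesions** — zero a tract's weights without refitting and
  compare the per-voxel r.m.s. error distributions in the tract's voxels
  (earth mover distance, bootstrap strength of evidence);
* **crossing-angle geometry** — pairwise axial angles between tracts (or a
  tract and its path-neighborhood) read directly off the tensor's
  orientation mode, summarized by peak angle μ and width at half height σ;
* **a synthetic phantom** — multi-bundle crossing geometry with known
  ground-truth weights, exact forward-model signal and Rician/Gaussian
  noise at a stated SNR, which powers every test;
* **I/O** — NIfTI volumes, FSL `bvals`/`bvecs`, TCK/TRK streamline files,
  plain-text tract index lists, and a versioned model container.

See the methods vignette (`vignettes/connectome-evaluation.Rmd`) for the
model, the encoding design and all numerical choices.

## Worked example

```r
library(lifet)

## a 15^3-voxel phantom: three 60-fascicle bundles crossing at 0/45/90
## degrees plus 20 spurious curves, 90 directions at b = 2000 s/mm^2, SNR 20
cfg   <- phantom_config(seed = 42L)
ph    <- life_phantom(cfg)
model <- life(ph$dwi, ph$tg, L = 362,
              control = life_control(tol = 1e-8, max_iter = 1000L))
summary(model)
#> LiFE model summary
#>   Phi: 362 x 678 x 200, nnz = 52704 (3294 fascicle-voxel incidences)
#>   memory: dense-equivalent 93.1 MB, factorized 1.25 MB (74x)
#>   connectome resolution (fascicles with w > 0): 191
#>   global rms error (occupied voxels): 0.04567
#>   solver: 122 iterations, objective change below tolerance
```

The fit keeps 191 of the 200 candidates; the global r.m.s. error (0.0457 on
the attenuation scale) sits at the noise floor of the SNR-20 simulation,
and the factorized model is 74× smaller than the explicit matrix would be.

```r
## statistical evidence for the first bundle: lesion it and compare errors
vl <- virtual_lesion(model, which(ph$labels == "bundle1"),
                     n_boot = 10000, seed = 1)
vl
#> Virtual lesion: |F| = 60 fascicles, 225 voxels, |P_F| = 130
#>   mean rms without lesion 0.04752, with lesion 0.09145
#>   EMD = 0.04393, strength of evidence = 26.23
```

Removing the bundle nearly doubles the prediction error in its 225 voxels —
an earth mover distance of 0.044 and a strength of evidence of 26 standard
errors: the data strongly support this tract.

```r
## crossing angles between the 0-degree and 45-degree bundles
ang <- pairwise_angles(model$tensor, model$dictionary,
                       which(ph$labels == "bundle1"),
                       which(ph$labels == "bundle2"),
                       weights = coef(model))
summarize_angles(ang)
#> Crossing-angle distribution: n = 1551, peak mu = 42.5 deg,
#>   width at half height sigma = 1.0 deg
```

The designed 45° crossing is recovered at 42.5° — within the orientation
quantization of a 362-atom dictionary — with a 1° half-height width.

A thin command-line wrapper over the same functions lives at
`inst/cli/lifet.R` (`phantom`, `encode`, `fit`, `evaluate`, `lesion`,
`angles` subcommands).

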