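# kneeseg

Benchmarking edge-detection segmentation algorithms for 3D bone-model
reconstruction from CT slice stacks.

Patient-specific finite-element (FE) analysis of the knee needs a 3D bone
surface, and that surface is only as good as the slice-wise segmentation it
was reconstructed from. `kneeseg` is for researchers who want to compare
segmentation algorithms (Sobel, Laplacian of Gaussian, Canny) against a
reference model — typically an expert manual segmentation — both
*morphologically* and through their effect on *downstream FE summaries*.

The package provides:

* **Segmentation** — Sobel gradient (the two 3×3 kernels, magnitude
  `G = √(Gx² + Gy²)`), Laplacian-of-Gaussian filtering
  `LoG(x,y) = (1/πσ⁴)(1 − (x²+y²)/2σ²) e^{−(x²+y²)/2σ²}` with zero-crossing
  edges (σ = 4 default), and full Canny (Gaussian smoothing σ = 2,
  non-maximum suppression, hysteresis at 0.10/0.90 of the maximum gradient),
  plus closing/fill/trace plumbing into closed mm-space contours.
* **Reconstruction** — contour rasterization (even-odd rule), shape-based
  slice interpolation, marching-tetrahedra isosurfacing, STL/PLY I/O.
* **Registration & deviation** — rigid ICP (point-to-surface, SVD fit),
  signed per-vertex deviations via angle-weighted pseudonormals, binned
  distributions, coverage at a threshold (default 0.227 mm), diverging
  blue–green–red color maps.
* **Material model** — incompressible Ogden strain energy
  `W = Σᵢ (μᵢ/αᵢ)(λ₁^αᵢ + λ₂^αᵢ + λ₃^αᵢ − 3)`, principal/uniaxial stresses,
  and Levenberg–Marquardt curve fitting for ligament-graft stress–strain
  data.
* **Error-rate metric** — per-flexion-angle discrepancy
  `η = Σᵢ |TMᵢ − RMᵢ|` over angles 0°/45°/90°/135°, with per-quantity
  winners and an overall method ranking.
* **Synthetic phantoms** — knee-scale cortical-tube phantoms with analytic
  ground-truth surfaces, partial-volume and noise models, so the entire
  pipeline is testable without patient data.

## Worked example

Segment a synthetic knee phantom with Canny, reconstruct the surface, and
score it against the analytic ground truth:

```r
library(kneeseg)

ph    <- generate_phantom(knee_phantom_spec(seed = 1))
stack <- segment_volume(ph$volume, method = "canny")
mesh  <- reconstruct_mesh(stack, spacing = ph$volume$spacing[1:2])
dev   <- deviation_map(mesh, ph$mesh)          # ICP, then signed distances
summarize_deviation(dev, threshold = 0.227)
#> <deviation_summary> n = 217132 vertices
#>   mean signed deviation: 0.0719 mm
#>   coverage |d| <= 0.227 mm: 56.18%
```

The mean signed deviation (here 0.07 mm) says the reconstruction carries no
systematic over- or under-estimation beyond a tenth of the 0.5 mm in-plane
voxel; the coverage says over half of all surface vertices lie within the
0.227 mm inspection threshold of the true surface.

Scoring methods on FE summary tables (one scalar per flexion angle per
method) and ranking them:

```r
tab <- read_angle_table(system.file("extdata", "table1_fe_summary.csv",
                                    package = "kneeseg"))
build_report(tab, reference = "Method 1",
             morphological = c("Method 2" = 0.0388, "Method 3" = 0.1081,
                               "Method 4" = 0.0117))
#> <error_rate_report> reference: Method 1
#>
#> Error rates (eta):
#>        quantity Method 2 Method 3 Method 4
#>       von_mises    1.428    1.439    1.152
#>  reaction_force    8.754    2.103    2.852
#>   contact_femur    6.487   10.756    2.966
#>   contact_tibia    2.227    1.192    2.409
#>
#> Ranking (by wins, then summed rank):
#>    method wins rank_sum
#>  Method 4    3        8
#>  Method 3    2       11
#>  Method 2    0       11
```

Method 4 (Canny) wins three of the five experiments (von Mises stress,
femur contact stress, morphology) and tops the ranking, ahead of Method 3
(LoG) and Method 2 (Sobel).

A thin command-line front end ships in `inst/cli/seg3d` with subcommands
`segment`, `reconstruct`, `compare`, `fit-material`, `error-rate`,
`make-phantom`, and `run`.

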