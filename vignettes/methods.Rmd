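---
title: "Benchmarking edge-detection segmentation for 3D bone reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking edge-detection segmentation for 3D bone reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeseg)
```

## The problem

Patient-specific finite-element models of the knee start from a 3D bone
surface reconstructed from a CT slice stack. The reconstruction hinges on
segmentation — delineating the bone boundary in every slice — which can be
done by a clinical expert or by an edge-detection algorithm. kneeseg
implements the three classical detectors used for this task (Sobel,
Laplacian of Gaussian, Canny), the reconstruction chain that turns stacked
contours into a triangulated surface, and two ways of scoring a
segmentation method against a reference model:

* **morphological**: rigid ICP alignment followed by per-vertex signed
  surface deviations and their distribution, and
* **functional**: a per-flexion-angle error rate `eta` over scalar FE
  outputs (von Mises stress, reaction force, contact stresses at 0, 45, 90,
  and 135 degrees of flexion), with a cross-method ranking.

The FE simulations themselves (contact, graft tensioning, flexion stepping)
are out of scope; their per-angle scalar summaries are consumed as input
tables.

## Slice-wise segmentation

All three detectors run on 2D axial slices.

* **Sobel** convolves the slice with the two 3x3 first-derivative kernels
  and takes the gradient magnitude `sqrt(gx^2 + gy^2)`. True convolution
  (kernel flipped) is used; both kernels are antisymmetric so this only
  changes signs, which the magnitude discards. A relative threshold
  (default 0.2 of the maximum magnitude) binarises the result, since the
  operator itself only yields magnitudes.
* **LoG** convolves with the Laplacian-of-Gaussian kernel
  `(1/(pi sigma^4)) (1 - r^2/(2 sigma^2)) exp(-r^2/(2 sigma^2))`, truncated
  at radius `ceiling(4 sigma)` (clamped to the image size) and shifted to
  sum exactly to zero, which guarantees a zero response on flat input.
  Edges are zero crossings whose jump exceeds 0.04 of the maximum absolute
  response; the literature gives no crossing rule, so this relative
  amplitude rule is a package choice. The default `sigma = 4` pixels
  follows the published operating point.
* **Canny** smooths with a Gaussian (`sigma = 2` by default), takes the
  Sobel gradient, thins it by non-maximum suppression along the quantised
  gradient direction (ties broken toward the lower index so a symmetric
  ridge keeps exactly one pixel), and applies double-threshold hysteresis
  with `low = 0.10` and `high = 0.90` *as fractions of the maximum smoothed
  gradient magnitude* — absolute values that large would be meaningless, so
  the fractions are read as relative. Weak pixels survive only in
  8-connected components that contain a strong pixel.

Relative thresholds make all detectors invariant to affine intensity
changes, which the test suite checks. They also have a failure mode on
slices that contain no bone at all: the slice maximum is then pure noise
and the detectors hallucinate structure. `segment_volume()` therefore gates
slices at stack level: a slice is segmented only if its maximum response
reaches 20% of the volume-wide maximum (`slice_gate`); below that it is
declared bone-free. Within a retained slice, thresholds are relative to the
slice's own maximum, which keeps partially attenuated slices (e.g. the
half-intensity slice at a bone end) detectable.

### From edge map to contours

Edge maps become closed polygons through morphological closing (3x3
square), hole filling, and connected-component selection (4-connectivity
for filled regions, 8-connectivity for edges; components below 50 pixels
are dropped). Two refinements matter for accuracy:

* **Band-midline correction.** Detector responses form a band that
  straddles the true boundary, so the filled region reaches to the *outer*
  side of that band. The region boundary is corrected by averaging the
  signed distance fields of the filled region and of the filled region
  with the edge band removed, placing the implied boundary on the band
  midline.
* **Sub-pixel placement.** Boundary tracing yields integer pixel centers,
  which sit systematically half a pixel inside the region's true boundary
  and carry a one-pixel staircase. Each traced vertex takes one Newton step
  onto the zero level of the midline field, and the polygon is smoothed
  with a short circular moving average (window 5). Without these steps the
  reconstructed surfaces show a 0.1-0.25 mm systematic bias — half the
  in-plane pixel — that would dominate the deviation statistics.

Contours are emitted in physical millimetres (`origin + index * spacing`,
0-based voxel indices).

## Surface reconstruction

`rasterize_contours()` fills contours back into a binary volume under the
even-odd rule (inner contours such as the medullary canal become holes).
`interpolate_slices()` performs shape-based interpolation: per-slice signed
Euclidean distance maps are interpolated linearly along the slice axis and
re-thresholded at zero, so intermediate cross-sections morph smoothly; the
default factor targets near-isotropic voxels
(`round(slice_spacing / in-plane spacing)`). `extract_surface()` runs
marching tetrahedra (each cube split into six tetrahedra sharing the main
diagonal — a decomposition that is watertight across cube faces by
construction) after a small Gaussian smoothing (`sigma = 0.5` voxels) of
the binary volume, which suppresses terracing; faces are oriented outward
and degenerate triangles dropped. Meshes round-trip through STL (ASCII and
binary) and PLY.

## Registration and deviation

`icp_register()` alternates exact point-to-surface correspondence (closest
point on a triangle, grid-accelerated) with a least-squares rigid fit via
the cross-covariance SVD, guarded against reflections. The objective — the
sum of squared closest-point distances — is non-increasing by construction
and iteration stops when the RMS improves by less than 1e-6 mm (at most
100 iterations). Sources with more than 5000 points are registered on an
evenly strided subsample; correspondence cost scales linearly in source
points and the rigid fit is over-determined long before that. Meshes from
the same CT frame start near-aligned, so the identity initialisation is
used; an explicit initial transform is accepted.

`deviation_map()` evaluates, per test-mesh vertex, the signed distance to
the reference surface; the sign comes from the reference's angle-weighted
pseudonormal at the closest point, which is well defined on faces, edges
and vertices. `summarize_deviation()` reports the mean signed deviation,
a binned distribution (13 equal bins across -1..+1 mm by default, values
beyond the span clamped into the outer bins so percentages always total
100), and the coverage — the share of vertices within a threshold
(0.227 mm by default, the inspection threshold used in the comparison this
package reproduces). `colorize_deviation()` maps deviations onto the
familiar blue (inside) - green (match) - red (outside) spectrum.

## The Ogden material model

The ACL graft in the downstream FE model is hyperelastic. kneeseg carries
the incompressible Ogden strain-energy density

`W = sum_i mu_i / alpha_i (lambda_1^alpha_i + lambda_2^alpha_i + lambda_3^alpha_i - 3)`

with principal stretches defined as the *square roots* of the eigenvalues
of the right Cauchy-Green tensor `C = F'F`. (Calling the stretches the
eigenvalues of `C` themselves, as sometimes written, contradicts
`J = lambda_1 lambda_2 lambda_3`; the square-root convention is the
standard one and is what the identity `J = det F` requires.) The raw
principal stresses `sigma_k = lambda_k dW/dlambda_k = sum_i mu_i
lambda_k^alpha_i` omit the hydrostatic pressure that incompressibility
leaves undetermined; both the raw form and the pressure-eliminated
differences `sigma_k - sigma_3` are available, the latter as default
because it is the mechanically meaningful quantity when direction 3 is
traction-free. Uniaxial response follows as
`sigma(lambda) = sum_i mu_i (lambda^alpha_i - lambda^(-alpha_i/2))`.

`fit_ogden()` fits this uniaxial form by Levenberg-Marquardt least squares
(minpack.lm) with bounds `mu > 0`, `0.1 < alpha < 40`, starting from
`mu = 1, alpha = 5`. No ligament coefficients are published for the source
comparison, so the synthetic generator defaults to `N = 1, mu = 1.5 MPa,
alpha = 8` — a ligament-like stiffening toe-region curve, explicitly a
package convention rather than a measured constant.

## The error-rate metric

For one scalar quantity measured at the four flexion angles, the error
rate of a test method against the reference is

`eta = sum_i |TM_i - RM_i|`, `i in {0, 45, 90, 135} degrees`.

The published formula is typographically ambiguous (it reads as an RMS but
reproduces none of the printed values under either RMS reading); the sum
of absolute differences reproduces **all twelve** printed values exactly,
so that interpretation is implemented as the default, with the two RMS
readings available behind `variant =` for sensitivity analysis. The test
suite ships the verification. `build_report()` scores every method on
every quantity, optionally adds a morphological experiment (winner: the
smallest absolute mean deviation), and ranks methods by win count with
ties broken by summed rank and then method id, so output is deterministic.

## The synthetic phantom

No CT data is deposited with the source comparison, so every stage is
exercised on phantoms with analytic ground truth. The default knee-scale
phantom is two parallel cortical tubes — a femur/tibia analogue — with
outer radii 22 and 18 mm, a 6 mm cortical wall, 30 mm length and an 8 mm
gap, on a 0.5 x 0.5 x 1 mm grid (thin-slice knee CT geometry; condyle-scale
radii). Intensity levels are Hounsfield-like conventions: background -100,
soft tissue 40, trabecular 300, cortical 1200. The soft-tissue compartment
fills the in-plane field of view over a z-range, as in a clinical scan
whose field of view sits inside the limb — consequently soft/air edges
never appear in-plane, which mirrors real knee CT and keeps the in-plane
segmentation problem about bone.

Partial volume is modelled *analytically*: each tissue boundary enters the
voxel intensity through a Gaussian-CDF ramp of its signed distance (width
`blur_sigma = 0.4 mm`), rather than by blurring a pre-quantised label
volume. This keeps sub-voxel surface positions in the data — a label-based
renderer snaps faces to the voxel lattice and introduces up to half a
voxel of spurious ground-truth error. Seeded Gaussian noise (sd 20) is
added last; the generator saves and restores the global RNG state.

Ground-truth meshes are parametric triangulations of the analytic
surfaces; tube and cone caps are triangulated as fans over rim vertices so
every vertex lies exactly on the analytic surface.

What passing the phantom tests shows — and what it does not: the phantom
has circular cross-sections, piecewise-constant tissue intensities and
stationary Gaussian noise. Real CT adds anatomy-specific curvature,
intensity inhomogeneity, beam hardening and contact between bones, so
phantom accuracy is a necessary, not sufficient, indicator for clinical
data.

## Numerical choices and scale

* Convolution: direct shift-and-add for kernels up to 5x5 (bitwise-exact
  zero on flat input), FFT with reflect padding otherwise; responses below
  1e-9 of the intensity scale are treated as zero.
* Marching tetrahedra nudges values exactly at the iso level by 1e-12 of
  the data range to avoid degenerate crossings.
* ICP convergence: RMS improvement below 1e-6 mm, at most 100 iterations;
  registration subsample 5000 points.
* Default problem sizes keep the full suite comfortably interactive: the
  knee phantom is 196 x 108 x 40 voxels and one segmentation-to-deviation
  pass takes on the order of tens of seconds per method; unit tests use
  smaller single-tube phantoms (56 x 56 x 16).

On the default phantom all three detectors reconstruct the surface with a
mean signed deviation well inside the in-plane voxel size and with the
majority of vertices within the 0.227 mm inspection threshold; the
remaining error is dominated by the bone end-caps, whose position along
the slice axis is only determined to the 1 mm slice spacing — an inherent
limit of slice-stacked reconstruction, visible in any such pipeline.

## Known limitations

* DICOM series input is not supported (no DICOM reader is available to
  this package); volumes arrive as NIfTI, TIFF stacks, or in-memory
  arrays.
* The slice-interpolation algorithm used by the original commercial
  reconstruction software is undocumented; shape-based interpolation is a
  stated substitute, not a claim of equivalence.
* `eta` compares methods on four angles only; no hypothesis testing is
  attached to the ranking, matching the source comparison's design.
* Boundary tracing assumes regions wider than one pixel; hairline regions
  may yield non-simple polygons.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(knee_phantom_spec(seed = 1))
stack <- segment_volume(ph$volume, method = "canny")
mesh <- reconstruct_mesh(stack, spacing = ph$volume$spacing[1:2])
dev <- deviation_map(mesh, ph$mesh)
summarize_deviation(dev)
autoplot(summarize_deviation(dev))
```
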