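---
title: "Measuring meniscal motion under knee load: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meniscal motion under knee load: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Under varus or valgus stress the menisci translate by fractions of a
millimetre up to about two millimetres, mostly within the tibial plateau
plane. Quantifying that motion from two 3D MRI scans of the same knee — one
unloaded, one loaded — is a registration problem with three stages:

1. **Rigid alignment relative to the tibia.** The whole leg shifts between
   scans. A rigid transform estimated *only from the tibial bone mask*
   expresses both scans in one tibia-fixed coordinate frame, so every
   subsequent displacement is motion relative to the tibia, not residual leg
   repositioning.
2. **Deformable registration of the meniscal region.** A dense displacement
   field $u$ on the unloaded scan's grid is estimated by minimising

   $$J(u) \;=\; \tfrac12\,\overline{\big(M(x+u(x)) - F(x)\big)^2}\Big|_{x \in \Omega}
   \;+\; \alpha\,\tfrac12\,\overline{\sum_c (\Delta u_c)^2}
   \;+\; \beta\,\overline{D\big(p+u(p)\big)^2}\Big|_{p \in S},$$

   where $F$ and $M$ are the unloaded and (aligned) loaded images,
   $\Omega$ is the union of the unloaded meniscus masks dilated by a few
   millimetres, $\Delta$ is the spacing-aware 6-neighbour vector Laplacian
   with zero-flux boundaries (the *curvature* regulariser), $S$ is the set
   of unloaded meniscal surface voxels, and $D$ is the Euclidean distance
   transform of the loaded-scan meniscus contour. Each term is a
   per-voxel / per-point mean, so the weights $\alpha$ and $\beta$ do not
   depend on grid size. The problem is solved with a multilevel, matrix-free
   Gauss–Newton scheme: conjugate gradients apply the Gauss–Newton operator
   block by block without assembling a matrix, an Armijo backtracking line
   search guarantees a monotone objective, and a coarse-to-fine pyramid
   supplies large-displacement robustness.
3. **Motion decomposition.** Displacement vectors are cropped to the
   meniscal masks. The medio-lateral (ML) and anterior-posterior (AP) axes
   are the first two principal components of the pooled unloaded meniscal
   voxel coordinates, signed so that +ML points laterally (medial-to-lateral
   centroid direction) and +AP posteriorly (from the image orientation).
   Each meniscus is split into anterior horn (AH), intermediate part (IP)
   and posterior horn (PH) by cutting its centerline at equal thirds of arc
   length, and per-scope mean vectors are projected on the axes.

The package exposes the stages individually (`register_rigid_masked()`,
`register_multilevel()`, `compute_axes()`, `partition_meniscus()`,
`summarize_motion()`) and as one fitting call, `fit_meniscus_motion()`,
whose result supports `summary()`, `coef()`, `predict()`, `residuals()` and
`plot()`. `run_case()`/`run_cohort()` wrap the chain with artifact and
provenance handling.

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `alpha` | 1.0 | – | curvature weight; smoothness of $u$ |
| `beta` | 0.3 | – | surface-distance penalty weight |
| `levels` | 3 | – | maximum pyramid levels (factor 2 each) |
| `ssd_region_dilation_mm` | 2 | mm | dilation of the meniscal masks defining $\Omega$ |
| `image_interpolation` | cubic | – | image model of the similarity term (Catmull–Rom or trilinear) |
| `step_tol` | 1e-4 | – | relative objective decrease that stops a level |
| `max_iter` | 50 | – | Gauss–Newton iterations per level |
| `cg_max_iter`, `cg_tol` | 30, 1e-2 | – | inner conjugate-gradient effort |
| `bin_deg` | 5 | deg | angular bin width of the centerline extraction |

The weight defaults were calibrated on phantom recovery experiments (below).
`beta = 0.3` deserves a note: the surface term is the only part of the
energy that anchors *drift modes* — near-uniform displacements of a whole
meniscus along its tangent, which cost almost no curvature and almost no
SSD on a thin, weakly textured structure. At `beta = 0` a zero-motion scan
pair drifts by ~0.3 mm mean displacement purely by fitting noise along
those modes; `beta = 0.3` holds the null case below 0.08 mm while leaving
the AP projections of real motions undistorted (weights $\geq 1$ visibly
drag tangential components toward the nearest-contour match and are not
recommended).

Two definitions of the reported `Avg` are available. The default is the
Euclidean norm of the mean displacement vector, the most literal reading of
"average the voxel motions, then project"; `avg_per_voxel_norm = TRUE`
instead averages per-voxel norms, which is never smaller and differs when
within-scope motion is heterogeneous. The default satisfies
`avg_mm == sqrt(ml_mm^2 + ap_mm^2 + si_mm^2)` exactly, and therefore also
`avg_mm >= sqrt(ml_mm^2 + ap_mm^2)`, a structural property of any table
reporting a 3D mean with only two printed projections.

## Numerical choices

* **Intensity normalisation.** Before optimisation both images are divided
  by the standard deviation of the fixed image over $\Omega$. This makes the
  default $\alpha$, $\beta$ meaningful regardless of scanner intensity
  units; without it the data term's scale (intensity²) would dwarf or be
  dwarfed by the regulariser depending on the acquisition.
* **Warm start from mask moments.** Each compartment's field is initialised
  with the translation between the centroids of its unloaded and loaded
  masks, blended to zero by a cosine ramp outside the mask. A meniscus is a
  ~3 mm-thick structure: after two pyramid decimations (2.4 mm voxels) it is
  barely resolved, so a purely coarse-to-fine search systematically
  under-recovers displacements beyond about one fine-grid voxel. The masks
  are already inputs of the method (they define $\Omega$, $S$ and $D$), so
  the moment initialisation uses no extra information.
* **Surface penalty direction.** The penalty pushes *unloaded* surface
  points through $u$ into the distance transform of the *loaded* contour.
  This is the one-sided form consistent with the data term's sampling
  direction $M(x+u(x))$; pushing loaded surface points through $+u$ into the
  unloaded contour's map would reward the sign-opposite field of what the
  similarity term rewards. Squared distances keep the term compatible with
  Gauss–Newton least squares.
* **C¹ image model with exact gradients.** The similarity term samples the
  moving image with Catmull–Rom cubic interpolation by default and
  differentiates the interpolant analytically, so finite-difference checks
  agree to numerical precision and the Gauss–Newton model is consistent
  with the sampled objective. The piecewise-linear model (available as
  `image_interpolation = "linear"`) has discontinuous gradients across cell
  boundaries and larger edge residuals, which measurably worsens sub-voxel
  recovery on thin structures; for the same reason the rigid stage
  resamples the loaded scan with Catmull–Rom before the deformable stage.
* **Pyramid resolvability rule.** A pyramid level whose downsampled
  meniscus masks retain no interior voxel (one-voxel erosion empties them)
  is dropped: at 2.4 mm spacing a ~3 mm-thick meniscus exists only as
  partial volume, and experiments showed such levels feeding systematically
  biased estimates to the finer levels instead of guiding them. For
  meniscus-scale structures this typically leaves one or two levels; the
  mask-moment warm start supplies the large-displacement robustness that
  coarse levels would otherwise contribute.
* **Solution domain.** The deformable problem is solved on a bounding box
  around both meniscal regions plus a margin; the returned field is zero
  outside. Vectors outside the menisci are cropped before analysis, so this
  only removes provably irrelevant unknowns (about 30-fold fewer). Because
  the curvature term is a per-grid-voxel mean, `alpha` is rescaled by the
  domain-size ratio so the cropped problem keeps exactly the full-grid
  energy density.
* **Levenberg damping.** The Gauss–Newton operator adds a small multiple
  (1e-2) of the mean data-block diagonal to its spectrum, bounding steps
  along directions the residuals barely constrain without measurably
  touching well-constrained ones.
* **Degenerate inputs.** Empty masks, grid mismatches, non-C-shaped or
  fragmented meniscus masks, and rank-deficient PCA point clouds are
  rejected with specific errors rather than propagated. CG directions that
  fail the descent test fall back to steepest descent; a failed line search
  terminates the level with the last accepted (never worse) iterate.
* **Ties and orientation.** Voxel-to-centerline assignment breaks ties
  toward the lower arc length; the AH end is the centerline endpoint with
  the smaller AP coordinate (more anterior). The PCA supplies axis lines
  only; signs come from anatomy (centroids) and header orientation, which is
  what makes left and right knees report "+ML = lateral" consistently.

# The synthetic knee phantom

No imaging cohort ships with the package, so validation uses a phantom
generator (`phantom_spec()`, `generate_case()`) that emulates the
*statistical structure* of loaded-knee MRI pairs:

* a tibial slab with an elliptical, anteriorly bumped cross-section (a
  rotationally symmetric shaft would make the tibia-masked rigid rotation
  about the shaft axis unobservable — no real tibia is such a solid of
  revolution);
* two femoral condylar half-ellipsoids and thin cartilage layers;
* two mirrored C-shaped meniscal tubes (torus segments) between them, with a
  smooth ±15% along-arc intensity modulation. The modulation mirrors the
  horn-to-body signal variation of real menisci and matters for
  identifiability: a perfectly homogeneous tube gives any intensity-driven
  registration no information about motion along the tube tangent (the
  aperture problem), which is an artifact of over-idealised geometry rather
  than a property of knee MRI;
* a whole-leg rigid repositioning between scans, and a per-compartment
  constant meniscal displacement (specified in anatomical ML/AP/SI
  components) blended to zero over a 5 mm cosine falloff, plus an optional
  low-frequency sinusoidal perturbation;
* independent Gaussian noise in each scan.

The loaded scan is synthesised by resampling the clean unloaded scan through
the *exact inverse* of the forward motion map $x \mapsto x + u(x)$
(fixed-point iteration; the falloff bound `falloff_mm >= 1.6 |u|` keeps the
map diffeomorphic). This guarantees $M(x+u(x)) = F(x)$ up to noise and
interpolation, i.e. the stored truth field is exactly the field an ideal
registration should recover. Naively warping "backwards" with $u$ itself
looks similar but encodes a *smaller* apparent motion wherever $u$ varies
over a displacement-sized neighbourhood — on 1.5–2 mm motions of a 1.5 mm
tube the apparent-truth mismatch reaches several tenths of a millimetre.

What the phantom does **not** emulate: MR physics (coils, sequences, bias
fields, motion artifacts), wedge-shaped meniscal cross-sections,
segmentation errors (masks are exact by construction), and deformation of
cartilage and bone. Passing recovery tests on phantoms therefore shows the
*pipeline's* correctness and conditioning, not robustness to acquisition or
segmentation pathologies of clinical data.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run, among unit-level checks:

* brute-force oracle comparisons of all three energy terms and
  finite-difference gradient checks on random 8³ grids;
* rigid recovery of a 3°/−2°/4°, 2.5/−1/0.5 mm whole-leg offset;
* deformable recovery on ten phantoms with per-compartment displacement
  magnitudes drawn uniformly from 0.5–2.0 mm (the range reported for
  loaded-knee meniscal motion), uniform in-plane direction, ±0.2 mm SI
  component and a 0.2 mm smooth perturbation;
* a low-overlap experiment (2 mm displacement of a 1.5 mm-radius tube) with
  and without the surface penalty;
* partition geometry on a semicircular tube of radius 20 mm, where each
  arc-length third must measure π·20/3 mm within one voxel;
* sign-convention checks on left- and right-sided phantoms;
* an end-to-end run recovering a (1.2, 0.4, 0) mm compartment motion;
* byte-level determinism of repeated seeded runs.

Phantom experiments use 64×64×48 grids at 0.6 mm spacing with the anatomy
scaled into that field of view (arc radius 6 mm, compartment offset
6.5 mm) — the same voxel resolution and motion scale as the study setting,
with a margin chosen so the loaded-scan menisci never leave the grid. The
full-size default (96³, arc radius 9 mm) behaves identically but is several
times slower, which matters for a test suite that runs the deformable solver
over a dozen times.

# Known limitations

* **Tangential shrinkage on thin homogeneous structures.** Even with the
  along-arc texture, the energy's minimiser slightly under-estimates motion
  components along the tube tangent (a few percent up to ~10% for
  AP-dominant motions of the smooth phantom); the curvature term couples the
  thin constant-motion core to its zero-motion surround. Mean endpoint
  errors stay below 0.3 mm in the study's motion range, but users comparing
  compartment magnitudes should expect a conservative (shrinking, not
  inflating) bias.
* **Resampling of the loaded scan.** The rigid stage resamples the loaded
  image once before deformable registration; on phantoms this extra
  interpolation adds of the order of 0.1 mm endpoint error relative to
  pre-aligned pairs.
* **One-sided surface penalty.** Matching unloaded surface to loaded
  contour is cheap and adequate for study-scale motions; a symmetric
  variant would be preferable for much larger deformations or topology
  differences between the masks.
* **No diffeomorphic guarantee.** The estimated field is regularised but
  not constrained to positive Jacobian determinant; at study-scale motions
  this has not been observed to matter on phantoms.
* **Statistical scope.** Cohort aggregation reports means and standard
  deviations per compartment cell only; no hypothesis testing is performed
  or implied.
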