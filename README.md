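# menisci

Quantifies in vivo motion of the medial (MM) and lateral (LM) meniscus
between an unloaded and a varus/valgus-loaded 3D knee MRI scan of the same
subject, the way orthopaedic imaging studies report it: per meniscus and per
compartment (anterior horn AH, intermediate part IP, posterior horn PH), as
a total displacement `Avg` with signed medio-lateral (`ML`, + = lateral) and
anterior-posterior (`AP`, + = posterior) projections, in millimetres.

The measurement chain:

1. **Tibia-masked rigid alignment** — a rigid transform estimated from SSD
   over the tibial bone mask only puts both scans in a tibia-fixed frame.
2. **Variational deformable registration** — a dense displacement field `u`
   minimises masked SSD + α·curvature (squared vector Laplacian) +
   β·surface-distance penalty, the last computed from a Euclidean distance
   transform of the loaded-scan meniscus contours. A multilevel matrix-free
   Gauss–Newton solver (conjugate gradients on the normal equations, Armijo
   line search) handles low initial mask overlap.
3. **Motion decomposition** — vectors are cropped to the meniscal masks;
   ML/AP axes come from a PCA of all unloaded meniscal voxels; each meniscus
   is partitioned into AH/IP/PH thirds of equal centerline arc length; mean
   vectors per scope are projected on the axes.

Inputs are NIfTI volumes with per-structure label masks (femur, tibia,
cartilages, menisci); an uncompressed MetaImage (`.mha`) dialect is also
read. A synthetic knee phantom generator with analytically known
ground-truth motion (`phantom_spec()`, `generate_case()`) supports
validation and examples.

## Worked example

```r
library(menisci)

# a simulated subject: 64x64x48 voxels at 0.6 mm, whole-leg repositioning
# of 2/-1.5/1 deg + 2/-1/1.5 mm between scans, and a known meniscal motion
# of 1.2 mm lateral + 0.4 mm posterior in both compartments
spec <- phantom_spec(grid_shape = c(64, 64, 48), spacing = c(0.6, 0.6, 0.6),
                     meniscus_arc_radius = 6, compartment_offset = 6.5,
                     meniscal_motion = list(medial = c(1.2, 0.4, 0),
                                            lateral = c(1.2, 0.4, 0)),
                     perturbation_amplitude = 0, seed = 3)
case <- generate_case(spec)

fit <- fit_meniscus_motion(case$reference$volume, case$moving$volume,
                           case$reference$structures, case$moving$structures)
summary(fit)
```

```
 meniscus   scope avg_mm ml_mm ap_mm  si_mm n_voxels
       MM Overall  1.136 1.072 0.376 -0.006      846
       MM      AH  1.011 0.914 0.432  0.000      306
       MM      IP  1.216 1.162 0.357 -0.009      234
       MM      PH  1.209 1.162 0.335 -0.009      306
       LM Overall  1.249 1.191 0.375  0.005      846
       LM      AH  1.297 1.228 0.415  0.018      306
       LM      IP  1.261 1.221 0.315  0.001      234
       LM      PH  1.194 1.131 0.382 -0.005      306
```

The simulated truth was ML 1.2 / AP 0.4 mm in both compartments: the
Overall rows recover it to 0.13 mm (ML) and 0.03 mm (AP) through the full
chain, with the expected mild conservative bias on thin structures (see the
methods vignette). `avg_mm` is the norm of the mean (ML, AP, SI) vector, so
`avg_mm >= sqrt(ml_mm^2 + ap_mm^2)` holds in every row. `coef()`
returns the 8×4 matrix, `predict()` warps the aligned loaded scan onto the
unloaded anatomy, `residuals()` gives the remaining intensity mismatch in
the meniscal region and `plot()` shows the per-level objective trace.

For file-based runs and cohorts:

```r
cfg <- run_config(output_dir = "out/case01",
                  fixed_path = "unloaded.nii.gz", moving_path = "valgus.nii.gz",
                  fixed_structure_paths = c(tibia = "...", medial_meniscus = "...", ...),
                  moving_structure_paths = c(...))
fit <- run_case(cfg)          # writes summary.csv, trace.csv, field.nii.gz,
                              # provenance.json
run_cohort(list(cfg1, cfg2), "cohort.csv")  # mean +/- SD per table cell
```

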