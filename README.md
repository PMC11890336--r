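# sonopath

Registration of resected-specimen 3D ultrasound slices to histopathology
whole-slide images (WSI), with resection-margin measurement and agreement
analysis.

## The problem

In oncological surgery of the tongue, intraoperative ultrasound of the
resected specimen can assess resection margins while the patient is still on
the table — but the tumor is hard to delineate in ultrasound, and
histopathology remains the diagnostic gold standard. If the ultrasound slice
can be registered to its corresponding H&E whole-slide image, the
pathologist's tumor annotation (HTA) can be carried back into the ultrasound
frame, yielding histopathology-grade ground-truth labels for ultrasound —
for margin assessment and for training segmentation networks.

`sonopath` implements that workflow for R users:

1. **Landmark registration with leave-one-out validation.** Each slice pair
   carries circumferential landmarks visible in both modalities plus up to
   three fiducial markers (cannula tracks along the specimen's long axis).
   Four point lists are formed — (1) circumferential only, (2) + left and
   middle fiducials, (3) + left and right, (4) + middle and right — and a
   transform `T_M` (similarity by default: rotation, isotropic scale,
   translation; the scale absorbs fixation shrinkage) is estimated for each
   by closed-form least squares (SVD of the centered cross-covariance). Each
   variant is scored by the **target registration error** at the fiducials
   withheld from its training set,

   `TRE = sqrt((US_x − PA_x)² + (US_y − PA_y)²)`,

   averaged over the validation markers; the transform with the lowest TRE
   wins.
2. **Annotation transfer.** The HTA polygon is mapped through `T_M⁻¹` into
   the ultrasound frame (`US_Reg`), kept as a vector contour and rasterized
   only on demand.
3. **Margin measurement.** Cranial, deep and caudal resection margins
   (minimum tumor-to-specimen-boundary distance inside angular wedges about
   the tumor centroid) and tumor thickness (extent along the deep axis), for
   three annotation sources: the manual ultrasound annotation (`US_M`), the
   registered HTA (`US_Reg`), and the HTA measured natively in the WSI.
4. **Agreement statistics.** Spearman rank correlation (exact permutation
   p for n ≤ 9) and Bland–Altman limits of agreement (mean ± 1.96 SD of the
   differences), overall and split by the mean-measurement categories
   < 5, 5 < 10 and > 10 mm.
5. **Segmentation metrics.** Dice coefficient, average surface distance and
   95th-percentile Hausdorff distance (pooled symmetric surface distances,
   2D or 3D, anisotropic spacing honored).

Patient data of this kind are not public, so the package ships a **synthetic
phantom generator** with known ground truth: a smooth specimen
cross-section with an embedded tumor and collinear fiducial defects, a
histology counterpart produced by a known similarity transform (default
shrinkage 0.90) plus optional smooth residual deformation, Gaussian landmark
selection jitter, and a noisy "manual" ultrasound annotation. Every
downstream stage is validated against this ground truth.

## Worked example

```r
library(sonopath)

spec <- phantom_spec(seed = 42, n_patients = 2, slices_per_patient = 2)
out  <- generate_specimen_slice(spec, patient_index = 1, slice_index = 1)

reg <- register_slice_pair(out$pair)
print(reg)
#> <registration_result: best variant 3, TRE 0.0177 mm>
#> per-variant TRE (mm): 1=0.0538  2=0.0692  3=0.0177  4=0.0805

meas <- measure_all(out$pair, reg)
print(meas, digits = 3)
#>    slide_id source    region value_mm
#> 1   P01_S01   US_M   cranial     2.63
#> 2   P01_S01   US_M      deep     0.38
#> ...
#> 9   P01_S01    WSI   cranial     2.07
#> 12  P01_S01    WSI thickness     9.14
```

Variant 3 (circumferential landmarks + left and right fiducials, validated
on the withheld middle fiducial) gives the lowest leave-one-out TRE,
0.018 mm, under the default 0.1 mm landmark jitter. The measurement table
shows the three annotation sources: `US_M` carries the simulated manual
annotation error (its deep margin, 0.38 mm, underestimates the registered
value of 1.31 mm), while the WSI values run ~10% smaller than the
ultrasound values — the built-in shrinkage. Agreement over many slides:

```r
cfg <- run_config(phantom = phantom_spec(seed = 7), n_excluded = 3)  # 29 slides
res <- run_study(cfg)
subset(res$agreement, stratum == "All")
#>   us_source stratum   n   rho .. mean_diff_mm loa_lower_mm loa_upper_mm
#>        US_M     All 116 0.909           0.41        -2.05         2.87
#>      US_Reg     All 116 0.971           0.55        -0.32         1.43
```

Registration narrows the 95% limits of agreement (width 4.9 → 1.8 mm) and
strengthens the correlation with histopathology — the pattern that
motivates using registered histopathological annotations as ultrasound
ground truth.

A command-line wrapper with `phantom`, `register`, `seg-eval` and `run-all`
subcommands is installed at `inst/cli/sonopath.R`.

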