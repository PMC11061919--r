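# trabmorph

Quantifying trabecular (spongy) bone microarchitecture from 3D CT volumes.
Bone strength depends not only on mineral content but on the geometry of the
trabecular network; `trabmorph` is aimed at researchers who validate
clinical-resolution CT devices (HR-pQCT, CBCT, MSCT) against micro-CT for
such measurements, and at anyone who needs the standard 3D structure
parameters from a segmented or grayscale volume.

## What it computes

Given a grayscale volume with isotropic voxel spacing and a binary volume of
interest (the trabecular compartment, cortical bone excluded), the pipeline
segments bone from marrow, skeletonizes it, and reports ten numbers:

| parameter | meaning |
|---|---|
| BVTV | bone voxels / VOI voxels |
| Tb.Th, s(Tb.Th) | mean and SD of trabecular thickness (mm) |
| Tb.Sp, s(Tb.Sp) | edge-to-edge separation of trabeculae (mm) |
| Tb.Sc, s(Tb.Sc) | midline-to-midline spacing (mm) |
| Tb.Nd | skeleton intersections per mm^3 |
| Tb.Tm | free skeleton ends per mm^3 |
| CNR | (skeleton mean − marrow mean) / marrow SD |

Segmentation is either **automated region growing (ARG)** — bone and marrow
regions grow alternately from bright/dark intensity seeds under a
homogeneity threshold `t`; `t` is swept over a schedule and the partition
maximizing the mean of the two region homogeneities `1 − sd(region)/sd(VOI)`
is kept — or **Otsu thresholding** for high-CNR data such as micro-CT.
Thickness, separation and spacing come from maximal-inscribed-sphere local
maps on an exact Euclidean distance transform; the skeleton is a
topology-preserving 3D thinning.

For paired device studies the package computes Pearson correlations with
Fisher-z 95% confidence intervals (`tanh(atanh(r) ± 1.96/sqrt(n−3))`), R²
and p-values, Bland–Altman bias with 95% limits of agreement
(`bias ± 1.96·sd(d)`) and proportional-bias regression, and paired t-tests
with confidence intervals of the difference.

A phantom module generates plate/rod/mixed-lattice volumes with analytic
ground truth and emulates scanner resolution chains (Gaussian PSF, voxel
resampling, CNR-calibrated correlated noise), so the whole pipeline is
testable without scanner data.

## Worked example

```r
library(trabmorph)

# a plate phantom: 0.2 mm plates repeating every 1.0 mm, 50 um voxels
ph  <- make_phantom(phantom_spec("plate_stack", pitch_mm = 1,
                                 element_width_mm = 0.2,
                                 extent_mm = c(4, 4, 4),
                                 base_spacing_mm = 0.05))
res <- analyze(ph$volume, method = "otsu")
as.data.frame(res)
#>   BVTV Tb.Th s(Tb.Th) Tb.Sc   s(Tb.Sc) Tb.Sp s(Tb.Sp)     Tb.Nd Tb.Tm CNR
#> 1  0.2  0.15        0 0.925 0.04330127  0.75        0 0.078125      0 Inf
```

BVTV is exactly the voxel-count ratio 0.2. Tb.Th reads 0.15 mm — one voxel
below the true 0.2 mm, the documented accuracy of a centre-sampled inscribed
sphere on an even-width slab. Tb.Sp (0.75) and Tb.Sc (0.925) recover the
0.8 mm gap and 1.0 mm pitch to within one and two voxels. CNR is infinite
because the phantom is noise-free. Dispersions are zero (all plates
identical) except s(Tb.Sc), which reflects the slightly shorter gap where
the volume face bisects a plate.

Checking a printed correlation table from its r and n alone:

```r
ci <- pearson_ci_from_r(0.98, n = 23)
round(c(ci$ci_low, ci$ci_high), 2)
#> [1] 0.95 0.99
```

From the shell, `inst/cli/trabmorph` wraps the same functions:

```sh
trabmorph phantom --kind plate_stack --pitch-mm 1 --width-mm 0.2 \
          --spacing-um 50 --extent-mm 4 --out ph
trabmorph analyze --input ph.nii.gz --method arg --id S01 --out row.csv
trabmorph compare --reference microct.csv --test hrpqct.csv --out-dir tables/
```

`compare` writes Pearson-correlation, descriptive, paired-t-test and
Bland–Altman tables (CSV) plus per-parameter scatter/Bland–Altman plots,
pairing specimens by the `id` column.

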