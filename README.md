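# limbmetric

Geometry and statistics for validating smartphone-photogrammetry
reconstructions of prosthetic residual limbs against CT-derived ground
truth.

Clinicians fitting prosthetic sockets need residual-limb surface models that
are accurate to fractions of a millimetre and volumes repeatable to about a
percent, because diurnal limb-volume fluctuations of −1.5 % to +2 % already
alter socket fit. `limbmetric` implements the computational stages of a
low-cost photogrammetry workflow that targets those tolerances, together
with the complete validation framework used to certify it against
micro-CT reference scans of 3D-printed limb phantoms:

- **frames** — variance-of-Laplacian sharpness scoring of video frames and a
  moving-window median rule that retains only locally sharp frames; EXIF
  orientation normalization and 50 % alpha-matte binarization.
- **aruco** — metric scale from printed square fiducial tags: single-tag
  planar pose, two-stage Perspective-n-Point, joint Levenberg–Marquardt
  optimization of all tag and camera poses (root tag gauge-fixed), and
  Umeyama similarity alignment that rescales an arbitrary-scale
  structure-from-motion reconstruction into millimetres.
- **ctshell** — watertight outer-shell meshes from CT volumes: global Otsu
  threshold, slab-wise cavity-removing background propagation, exact signed
  Euclidean distance fields, Gaussian regularization and isosurface
  extraction, then Taubin smoothing.
- **register** — two-stage rigid alignment: FPFH descriptors with seeded
  RANSAC for the coarse stage, multi-scale point-to-plane ICP against the
  exact triangle surface for refinement.
- **clinmetrics** — the clinical metric suite on a region of interest
  clipped at anatomical landmark planes (MPT/BAR): mean radial error (MRE),
  RMSE, IQR, symmetric Hausdorff distance, mean angular error (MAE),
  per-slice perimeter errors (10 axial slices), relative ROI volume error
  (VErel), and threshold compliance
  (|MRE| ≤ 0.25 mm, IQR ≤ 0.4 mm, RMSE < 1 mm, Hausdorff ≤ 1.8 mm,
  MAE < 4°, |bias| ≤ 1 %, MDC < 3.5 %).
- **repeatability** — medoid-based inter-session repeatability: per-vertex
  SD/IQR/P95 maps and the pooled-SD minimal detectable change
  MDC = 1.96·√2·SD.
- **phantom** — parametric synthetic limb phantoms (conical, cylindrical,
  bulbous, ischial families) with analytic volumes and perimeters,
  controlled radial deformations, seeded vertex noise, voxelization with
  internal cavities, and exact pinhole tag projections — the oracle test bed
  for every other module.

The core signed-distance definition: for every test vertex `p`, the nearest
point `q` on the reference surface gives `d(p) = ±|p − q|`, signed by the
angle-weighted pseudonormal at `q`; then

```
MRE  = mean(d)              RMSE = sqrt(mean(d^2))
IQR  = Q3 − Q1 of d         Hausdorff = max over both directions of |d|
MAE  = mean angle between corresponding surface normals
VErel = (V_test − V_ref) / V_ref     MDC95 = 1.96 · sqrt(2) · SD
```

## Worked example

Inflate a synthetic limb phantom by a known 0.2 mm, register it back to the
original, and score it against the clinical thresholds:

```r
library(limbmetric)

ph   <- makePhantom(phantomSpec("ischial", crest = 0.12,
                                segments = 64, rings = 40))$mesh
test <- deformRadial(ph, 0.2)                    # ground-truth +0.2 mm
reg  <- registerMeshes(test, ph, seed = 1)
roi  <- roiSpec(c(0, 0, 1), c(0, 0, 0), 120, "MPT")
accuracyReport(applyTransform(test, reg@transform), ph, roi)
```

```
AccuracyReport: MRE 0.1997 mm, RMSE 0.1999 mm, IQR 0.0101 mm, Hausdorff 0.2132 mm, MAE 0.048 deg
  VErel 1.0784 %; mean perimeter error 0.4836 % (10/10 slices)
  compliance: mre=pass iqr=pass rmse=pass hausdorff=pass mae=pass overall=pass
```

The recovered MRE equals the injected inflation to within about 1 %; the
ROI volume error of ≈1 % is exactly what a 0.2 mm offset on a ~40 mm-radius
limb produces (VErel ≈ δ·S/V), and all global surface metrics sit inside
the clinical limits.

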