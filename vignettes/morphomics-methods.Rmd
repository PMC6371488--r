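---
title: "Methods: single-slice CT morphomics in ctmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-slice CT morphomics in ctmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmorph)
```

## The measurement model

Body-composition biomarkers are measured on a single axial CT slice at a
standardized anatomical level. Each marker is defined by a region (a binary
pixel mask) and a tissue attenuation window in Hounsfield units (HU). The
measured quantities are:

- area: the number of region pixels whose HU falls inside the window,
  times the pixel area (row spacing × column spacing, mm²);
- mean attenuation (`_HU` markers): the mean HU over those same pixels.

The windows are inclusive on both ends: fat [−190, −30] HU, lumbar-level
muscle [−29, 150] HU, thoracic-level muscle [−129, 150] HU. Sixteen markers
are cataloged (`marker_catalog()`): psoas (PMA), total lumbar (TLMA),
lumbar dorsal (LDMA) and total thoracic (TTLMA) muscle areas, visceral
(VFA), subcutaneous (SFA), total abdominal (TAA) and epicardial (EFA) fat
areas, plus their mean-attenuation counterparts.

Pixels store the raw value; HU are obtained with the DICOM rescale
transform `HU = stored * RescaleSlope + RescaleIntercept`. Slices of a
series are ordered by the projection of ImagePositionPatient onto the slice
normal (the cross product of the row and column direction cosines) — not by
InstanceNumber, which scanners do not guarantee to be spatial.

## Level selection

The axial level is chosen on a sagittal multiplanar reconstruction.
Because the in-plane axes of an axial series are aligned across slices, a
sagittal plane is an exact column extraction from each slice — no
interpolation is introduced (`sagittal_view()`), and the displayed aspect
ratio is slice gap / row spacing. `select_level()` accepts a 1-based slice
index or a millimetre position along the stack normal; a position exactly
between two slices resolves to the lower index.

## Automatic compartment segmentation

`segment_compartments()` separates subcutaneous from visceral fat in three
stages:

1. **Body outline.** Pixels above −500 HU, largest 8-connected component,
   interior holes filled. −500 HU sits far from both the fat window floor
   (−190) and air (−1000), so the outline is insensitive to realistic noise.
2. **Pseudo-polar wall detection.** From the body centroid, HU profiles
   are sampled along `n_rays = 360` rays in steps of 0.5 px
   (nearest-pixel lookup). Walking inward from the skin, the first run of
   at least `min_run_px = 3` consecutive muscle-window samples is taken as
   the abdominal wall; the run's outer and inner ends give per-angle wall
   radii. Rays that find no such run (e.g. through a hernia or rectus
   diastasis) get radii by circular linear interpolation from their
   neighbours, and all three radius profiles (skin, wall outer, wall
   inner) are smoothed with a circular median filter of width 5, which
   removes single-ray outliers — e.g. a ray that hits a small
   intramuscular fat fleck — without rounding corners.
3. **Compartments.** Subcutaneous fat: fat-window pixels outside the outer
   wall radius; visceral fat: fat-window pixels inside the inner wall
   radius. The wall band itself belongs to neither compartment, so a fat
   fleck inside the muscle wall counts toward total fat (TAA) but not
   toward SFA or VFA — TAA is measured independently as all fat-window
   pixels within the body outline (`segment_tat()`), which also makes
   `TAA − SFA − VFA` an index of intramuscular fat.

Muscle candidates (`tama`) are muscle-window pixels within the body;
note that on real scans this operational definition includes organs that
are isodense with muscle, so lumbar muscle area still requires either a
manual region or review of the automatic mask.

## The synthetic phantom

All tests run against `phantom_generate()`, a seeded generator of
abdominal phantoms with exact ground truth: an elliptical body (default
semi-axes 0.47 and 0.66 of the half grid), a muscle-wall annulus between
0.70 and 0.82 of the body semi-axes, a subcutaneous fat ring outside it, a
visceral core with smoothed-Gaussian-field fat blobs at a requested
fraction, psoas and vertebral ellipses, optional Gaussian HU noise, and a
visceral fat layer lining the inner wall. The lining mirrors the
peritoneal fat plane of real anatomy and is what terminates the wall run
at its true inner edge even though organ tissue (35 HU) is isodense with
muscle; without it, wall detection on the phantom would merge the wall
with the organ mass — the same failure mode a real scan without any
visceral fat would show. Class HU values (fat −95, muscle 45, organ 35,
bone 700, air −1000) sit inside their respective windows.

What the phantom deliberately does not emulate: partial-volume averaging
at tissue boundaries, beam hardening, table/clothing artifacts, and
anatomical asymmetry. It is a correctness instrument, not a realism
instrument: recovered areas are compared against the phantom's own
rasterized truth masks, and rasterized areas agree with the analytic
ellipse formulas to within 1% at the default 512-pixel grid.

Ground-truth comparisons for automatic segmentation are restricted to
SFA, VFA and TAA; the muscle-candidate mask is excluded because the
phantom's organ class is isodense with muscle by design (see above).

## Statistics

For paired measurements (two methods or readers over the same subjects):

- **Bland–Altman**: differences `a − b`; limits of agreement are the mean
  difference ± 1.96 sample standard deviations. Relative differences use
  the pairwise mean `(a+b)/2` as denominator; pairs with `a + b = 0` are
  excluded from the relative summary with a warning.
- **Spearman**: Pearson correlation of ranks, average ranks on ties;
  undefined (an error) when either side has zero rank variance.
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measure, computed from the subject/method/residual mean squares
  `(MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`. This variant is
  the appropriate one for method agreement because systematic bias between
  methods lowers it (a consistency ICC would not).
- **ICC test power**: for H₀: ICC = ρ₀ vs H₁: ICC = ρ₁ in a one-way
  design with n subjects and k measurements, with
  θ(ρ) = (1 + (k−1)ρ)/(1−ρ), the between/within mean-square ratio divided
  by θ(true ICC) is F(n−1, n(k−1)); power is
  P(F > θ(ρ₀)/θ(ρ₁)·F₁₋α). At ρ₀ = 0.90, ρ₁ = 0.99, n = 50, k = 2,
  α = 0.05 the power rounds to 100%.

Each statistic is tested against an independent oracle: hand-arithmetic
examples, the rank-difference formula, an `aov()`-based mean-square
computation, variance-ratio construction at large n, and a
100,000-replicate Monte-Carlo F simulation for the power formula.

## Numerical conventions

- Indices are 1-based everywhere (pixels, slices, instances).
- Ties in level selection by position resolve to the lower slice index.
- HU windows are inclusive at both endpoints.
- Brush and eraser discs use Euclidean distance between pixel centres,
  inclusive at the radius.
- Areas are reported to 2 decimals (mm² and cm²), attenuations to 1
  decimal, in a locale-independent CSV (dot decimal separator, LF line
  endings) that is byte-identical across runs and platforms.
- Mask PNGs store literal 0/1 byte values; any non-zero pixel is read
  back as 1.
- De-identification strips a fixed list of 12 identifying attributes plus
  every private (odd-group) element, and is idempotent.
- Problem sizes used in tests (grid sizes, ray counts, phantom geometry)
  are this package's own validation choices.

## Limitations

Single-slice markers are estimates of compartment volumes; their clinical
validity rests on level standardization, which this package supports but
cannot enforce. The wall detector assumes a star-convex body outline with
respect to the centroid — grossly non-convex anatomy (large ventral
hernias) degrades it, which is why per-angle radii, interpolation and
median smoothing are exposed as parameters rather than constants.
Compressed DICOM transfer syntaxes are rejected with a named error rather
than silently mis-read.
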